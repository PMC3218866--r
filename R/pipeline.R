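# Orchestration: simulate (or accept) three genomes, then run homology ->
# synteny -> RIP -> molecular evolution and collect one summary object.
# Every stage is an exported function; the pipeline only sequences them,
# so intermediate results can be recomputed or inspected in isolation.

#' Run the full three-genome comparison
#'
#' Stages: all-vs-all homology, reciprocal best hits and ortholog
#' triangles, Venn partition, Markov-cluster paralog families and
#' expansion report, pairwise synteny blocks and per-genome
#' syntenic/non-syntenic classification (a gene is syntenic if covered in
#' at least one pairwise comparison), ortholog-vs-synteny enrichment and
#' per-category enrichment, genome and repeat-family RIP indices, marker
#' Ka/Ks with rate comparisons, and the syntenic-vs-non-syntenic codon
#' usage check. Deterministic given the config seed.
#'
#' @param config a [clade_config()] (genomes are simulated), or a named
#'   list of exactly three `genome_annotation`s.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param hom_params,syn_params stage parameter objects.
#' @param n_markers marker triples used for rate estimation (default 50;
#'   capped at the number of eligible triples).
#' @return List of class `clade_comparison` with per-stage results and a
#'   `summary` list of headline numbers.
#' @export
run_full_comparison <- function(config, out_dir = NULL,
                                hom_params = homology_params(),
                                syn_params = synteny_params(),
                                n_markers = 50) {
  truth <- NULL
  if (inherits(config, "clade_config")) {
    sim <- simulate_clade(config)
    genomes <- sim$genomes
    truth <- sim$truth
    seed <- config$seed
  } else {
    stopifnot(is.list(config), length(config) == 3)
    genomes <- config
    seed <- 1
  }
  sp <- names(genomes)

  matches <- all_vs_all(genomes, hom_params)
  rbh <- list(AB = reciprocal_best_hits(matches, sp[1], sp[2]),
              BC = reciprocal_best_hits(matches, sp[2], sp[3]),
              AC = reciprocal_best_hits(matches, sp[1], sp[3]))
  triples <- three_way_orthologs(rbh$AB, rbh$BC, rbh$AC)
  partition <- orthology_partition(genomes, triples, rbh)

  fams <- mcl_cluster(similarity_graph(matches))
  expansion <- expanded_families(fams, triples, sp)

  orders <- lapply(genomes, gene_order)
  pair_defs <- list(AB = c(1, 2), BC = c(2, 3), AC = c(1, 3))
  blocks <- list()
  for (pn in names(pair_defs)) {
    i <- pair_defs[[pn]][1]; j <- pair_defs[[pn]][2]
    anch <- rbh[[pn]][, c("gene_a", "gene_b", "score")]
    blocks[[pn]] <- build_blocks(orders[[i]], orders[[j]], anch, syn_params)
    # reverse axis: same anchors, swapped roles
    anch_rev <- data.frame(gene_a = anch$gene_b, gene_b = anch$gene_a,
                           score = anch$score)
    blocks[[paste0(pn, "_rev")]] <- build_blocks(orders[[j]], orders[[i]],
                                                 anch_rev, syn_params)
  }
  classify_union <- function(k) {
    ord <- orders[[k]]
    use <- switch(k, `1` = list(blocks$AB, blocks$AC),
                  `2` = list(blocks$AB_rev, blocks$BC),
                  `3` = list(blocks$AC_rev, blocks$BC_rev))
    cls <- lapply(use, function(b) classify_genes(ord, b, side = "a",
                                                  break_run = syn_params$break_run))
    covered <- Reduce(`|`, lapply(cls, function(d) d$class == "syntenic"))
    # gene syntenic if syntenic versus at least one other genome; the
    # break-run rule is then re-applied to the union coverage
    ord2 <- cls[[1]]
    ord2$class <- ifelse(covered, "syntenic", "non_syntenic")
    runs_fix(ord2, syn_params$break_run)
  }
  runs_fix <- function(cls, break_run) {
    # re-apply the >= break_run rule to the union: short non-syntenic runs
    # are tolerated back to syntenic
    for (sc in unique(cls$scaffold_id)) {
      idx <- which(cls$scaffold_id == sc)
      r <- rle(cls$class[idx] == "non_syntenic")
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (q in seq_along(r$lengths))
        if (r$values[q] && r$lengths[q] < break_run)
          cls$class[idx[starts[q]:ends[q]]] <- "syntenic"
    }
    cls
  }
  classification <- lapply(seq_along(genomes), function(k) classify_union(k))
  names(classification) <- sp
  class_all <- do.call(rbind, lapply(sp, function(s)
    cbind(species = s, classification[[s]], stringsAsFactors = FALSE)))

  # ortholog (core) x synteny enrichment per species (headline test)
  core_ids <- c(triples$gene_a, triples$gene_b, triples$gene_c)
  enrichment <- lapply(sp, function(s) {
    cls <- classification[[s]]
    is_core <- cls$gene_id %in% core_ids
    ns <- cls$class == "non_syntenic"
    # degenerate (e.g. fully syntenic) tables carry no information
    tryCatch(enrichment_2x2(sum(!ns & is_core), sum(!ns & !is_core),
                            sum(ns & is_core), sum(ns & !is_core)),
             error = function(e) NULL)
  })
  names(enrichment) <- sp

  categories <- do.call(rbind, lapply(genomes, function(g)
    g$genes[, c("gene_id", "category")]))
  cat_enrich <- lapply(sp, function(s)
    category_enrichment(classification[[s]], categories))
  names(cat_enrich) <- sp

  rip <- lapply(genomes, genome_rip_profile)
  rep_fams <- lapply(genomes, find_repeat_families)
  fam_rip <- lapply(sp, function(s)
    if (nrow(rep_fams[[s]]) > 0) family_rip_indices(genomes[[s]], rep_fams[[s]])
    else NULL)
  names(fam_rip) <- sp

  # marker-based rates: syntenic true-ortholog triples, seeded sample
  rates <- NULL; rate_tests <- NULL; markers <- NULL
  if (nrow(triples) > 0) {
    elig <- NULL
    for (nn in unique(pmin(c(n_markers, 20, 10, 3), nrow(triples)))) {
      elig <- tryCatch(select_phylogenomic_markers(
        triples, class_all, matches, n = nn, seed = seed),
        error = function(e) NULL)
      if (!is.null(elig)) break
    }
    if (!is.null(elig) && nrow(elig) >= 3) {
      markers <- elig
      cds_of <- function(g, ids) setNames(g$genes$cds, g$genes$gene_id)[ids]
      pairs <- list(AB = cbind(cds_of(genomes[[1]], elig$gene_a),
                               cds_of(genomes[[2]], elig$gene_b)),
                    AC = cbind(cds_of(genomes[[1]], elig$gene_a),
                               cds_of(genomes[[3]], elig$gene_c)),
                    BC = cbind(cds_of(genomes[[2]], elig$gene_b),
                               cds_of(genomes[[3]], elig$gene_c)))
      rates <- do.call(rbind, lapply(names(pairs), function(pn) {
        m <- pairs[[pn]]
        st <- lapply(seq_len(nrow(m)), function(r) ka_ks_pair(m[r, 1], m[r, 2]))
        data.frame(pair = pn, marker = seq_len(nrow(m)),
                   Ks = vapply(st, `[[`, 0, "Ks"),
                   Ka = vapply(st, `[[`, 0, "Ka"), stringsAsFactors = FALSE)
      }))
      ks_of <- function(pn) rates$Ks[rates$pair == pn]
      ka_of <- function(pn) rates$Ka[rates$pair == pn]
      rate_tests <- list(
        Ks_AC_vs_AB = rate_set_comparison(ks_of("AC"), ks_of("AB")),
        Ks_BC_vs_AB = rate_set_comparison(ks_of("BC"), ks_of("AB")),
        Ka_AC_vs_AB = rate_set_comparison(ka_of("AC"), ka_of("AB")),
        Ka_BC_vs_AB = rate_set_comparison(ka_of("BC"), ka_of("AB")))
    }
  }

  codon_usage <- lapply(sp, function(s)
    tryCatch(compare_region_codon_usage(genomes[[s]], classification[[s]]),
             error = function(e) NULL))
  names(codon_usage) <- sp

  pct_ns <- vapply(sp, function(s)
    100 * mean(classification[[s]]$class == "non_syntenic"), 0)

  summary <- list(
    species = sp,
    n_genes = vapply(genomes, function(g) nrow(g$genes), 0L),
    venn = as.list(partition$counts),
    pct_non_syntenic = as.list(pct_ns),
    n_blocks = vapply(blocks[c("AB", "BC", "AC")], nrow, 0L),
    mean_syntenic_identity = vapply(names(pair_defs), function(pn)
      tryCatch(mean_syntenic_identity(rbh[[pn]], class_all),
               error = function(e) NA_real_), 0),
    enrichment_p = vapply(enrichment, function(e)
      if (is.null(e)) NA_real_ else e$p_two_sided, 0),
    enrichment_or = vapply(enrichment, function(e)
      if (is.null(e)) NA_real_ else e$odds_ratio, 0),
    genome_rip = lapply(rip, function(r)
      list(ta_at = r$genome_wide$ta_at, composite = r$genome_wide$composite)),
    n_repeat_families = vapply(rep_fams, function(f)
      if (nrow(f)) length(unique(f$family_id)) else 0L, 0L),
    rip_positive_families = vapply(fam_rip, function(f)
      if (is.null(f)) 0L else sum(f$verdict == "rip_positive"), 0L),
    median_rates = if (!is.null(rates))
      lapply(split(rates, rates$pair), function(d)
        list(Ks = median(d$Ks, na.rm = TRUE), Ka = median(d$Ka, na.rm = TRUE)))
      else NULL,
    rate_test_p = if (!is.null(rate_tests))
      lapply(rate_tests, `[[`, "p_value") else NULL,
    cai_p = lapply(codon_usage, function(cu)
      if (is.null(cu) || cu$degenerate) NA_real_ else cu$comparison$p_value))

  res <- structure(list(
    genomes = genomes, truth = truth, matches = matches, rbh = rbh,
    triples = triples, partition = partition, families = fams,
    expansion = expansion, blocks = blocks, classification = classification,
    enrichment = enrichment, category_enrichment = cat_enrich, rip = rip,
    repeat_families = rep_fams, family_rip = fam_rip, markers = markers,
    rates = rates, rate_tests = rate_tests, codon_usage = codon_usage,
    summary = summary), class = "clade_comparison")

  if (!is.null(out_dir)) write_comparison(res, out_dir)
  res
}

#' @noRd
write_comparison <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) if (!is.null(df) && nrow(df))
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$matches, "matches.tsv")
  for (pn in names(res$rbh)) wt(res$rbh[[pn]], paste0("rbh_", pn, ".tsv"))
  wt(res$triples, "ortholog_triples.tsv")
  wt(res$families, "paralog_families.tsv")
  wt(res$expansion, "family_expansion.tsv")
  for (pn in c("AB", "BC", "AC"))
    wt(res$blocks[[pn]][, setdiff(names(res$blocks[[pn]]),
                                  c("genes_a", "genes_b"))],
       paste0("blocks_", pn, ".tsv"))
  for (s in names(res$classification))
    wt(res$classification[[s]], paste0("classification_", s, ".tsv"))
  for (s in names(res$repeat_families))
    wt(res$repeat_families[[s]], paste0("repeat_families_", s, ".tsv"))
  wt(res$rates, "marker_rates.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render a comparison summary as markdown
#'
#' Human-readable tables for the Venn partition, per-species synteny and
#' enrichment, RIP verdicts and rate medians; regenerates identically from
#' the same summary.
#'
#' @param summary the `summary` element of a `clade_comparison` (or the
#'   object itself).
#' @return Character scalar of markdown.
#' @export
render_report <- function(summary) {
  if (inherits(summary, "clade_comparison")) summary <- summary$summary
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("# Three-genome comparison report\n")
  if (!is.null(summary$species))
    add("Species: %s\n", paste(summary$species, collapse = ", "))
  if (!is.null(summary$venn)) {
    add("## Ortholog distribution\n")
    add("| cell | count |\n|---|---|")
    for (nm in names(summary$venn)) add("| %s | %s |", nm, summary$venn[[nm]])
    add("")
  }
  if (!is.null(summary$pct_non_syntenic)) {
    add("## Synteny\n")
    add("| species | %% non-syntenic | enrichment p (orth x synteny) |")
    add("|---|---|---|")
    for (i in seq_along(summary$pct_non_syntenic))
      add("| %s | %.1f | %.3g |", names(summary$pct_non_syntenic)[i],
          summary$pct_non_syntenic[[i]],
          if (!is.null(summary$enrichment_p)) summary$enrichment_p[[i]] else NA)
    add("")
  }
  if (!is.null(summary$genome_rip)) {
    add("## RIP indices (genome-wide)\n")
    add("| species | TA/AT | (CA+TG)/(AC+GT) | repeat families | RIP-positive |")
    add("|---|---|---|---|---|")
    for (s in names(summary$genome_rip))
      add("| %s | %.2f | %.2f | %d | %d |", s,
          summary$genome_rip[[s]]$ta_at, summary$genome_rip[[s]]$composite,
          summary$n_repeat_families[[s]], summary$rip_positive_families[[s]])
    add("")
  }
  if (!is.null(summary$median_rates)) {
    add("## Evolutionary rates (marker medians)\n")
    add("| pair | median Ks | median Ka |")
    add("|---|---|---|")
    for (pn in names(summary$median_rates))
      add("| %s | %.3f | %.3f |", pn, summary$median_rates[[pn]]$Ks,
          summary$median_rates[[pn]]$Ka)
    add("")
  }
  paste(ln, collapse = "\n")
}
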