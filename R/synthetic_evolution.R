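# Seeded three-species clade simulator with full ground truth.
#
# Topology is ((B,C),A): A diverges first (basal), B and C split later, and
# branch C carries elevated substitution rates, heavier gene loss and more
# rearrangement -- the pattern of a fast-evolving derived lineage. Genomes
# are represented internally as ordered segment lists (gene / spacer /
# transposable-element segments) so that inversions, duplications, losses
# and insertions stay coordinate-consistent; the segment list is assembled
# into scaffold sequence plus gene models at the end.

# First-order Markov transition matrix for intergenic and TE background
# sequence, tuned so that unmutated sequence has genome-like dinucleotide
# structure (TA/AT ~ 0.67, (CA+TG)/(AC+GT) ~ 1.23) rather than the uniform
# composition under which the composite RIP index has no headroom.
.bg_transition <- rbind(
  A = c(A = .28, C = .22, G = .28, T = .22),
  C = c(A = .30, C = .22, G = .26, T = .22),
  G = c(A = .26, C = .26, G = .26, T = .22),
  T = c(A = .16, C = .28, G = .30, T = .26))

#' @noRd
random_biased_dna <- function(n) {
  if (n <= 0L) return("")
  bases <- colnames(.bg_transition)
  out <- character(n)
  out[1] <- sample(bases, 1)
  for (i in seq_len(n - 1L))
    out[i + 1L] <- sample(bases, 1, prob = .bg_transition[out[i], ])
  paste(out, collapse = "")
}

#' @noRd
random_cds <- function(n_codons) {
  ct <- codon_tables()
  body <- sample(ct$sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Per-branch evolutionary parameters
#'
#' @param ka expected nonsynonymous substitutions per nonsynonymous site.
#' @param ks expected synonymous substitutions per synonymous site.
#' @param n_inversions number of gene-order inversions applied.
#' @param inversion_len_genes length range (genes) of an inversion.
#' @param n_duplications number of gene duplications.
#' @param n_losses number of gene losses.
#' @param te_insertions number of new transposable-element copies inserted.
#' @return List of class `branch_params`.
#' @export
branch_params <- function(ka = 0.03, ks = 0.10, n_inversions = 6,
                          inversion_len_genes = c(2, 6),
                          n_duplications = 8, n_losses = 4,
                          te_insertions = 3) {
  stopifnot(ka >= 0, ks >= 0, all(inversion_len_genes >= 1))
  structure(list(ka = ka, ks = ks, n_inversions = n_inversions,
                 inversion_len_genes = inversion_len_genes,
                 n_duplications = n_duplications, n_losses = n_losses,
                 te_insertions = te_insertions), class = "branch_params")
}

#' Configuration for a simulated three-species clade
#'
#' Defaults describe the study conditions the package is validated under:
#' three species on topology ((B,C),A) with branch C evolving roughly twice
#' as fast and losing three times as many genes, rearrangement dominated by
#' small (2-6 gene) inversions, lineage-specific duplications concentrated
#' in a few contiguous islands, and multicopy transposable elements degraded
#' by RIP-type CpA->TpA mutation on every branch.
#'
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @param n_genes genes in the ancestral genome.
#' @param n_scaffolds scaffolds in the ancestral genome.
#' @param gene_len_codons range of gene lengths in codons (incl. start/stop).
#' @param spacer_len range of intergenic spacer lengths in bp.
#' @param branches named list of [branch_params()] for branches `A`
#'   (ancestor to species A), `I` (internal), `B`, and `C`.
#' @param dup_target fraction of duplications placed into designated
#'   non-syntenic islands (the rest are tandem).
#' @param n_islands number of duplication islands designated per branch.
#' @param n_te_families ancestral transposable-element families.
#' @param te_copies_per_family copies of each family inserted ancestrally.
#' @param te_len_bp element length in bp (>= 400).
#' @param rip_rounds RIP rounds applied to every TE copy on every branch.
#' @param rip_prob per-round mutation probability per CpA (and TpG) site.
#' @param category_tags number of distinct PFAM-like category labels.
#' @param category_frac fraction of ancestral genes carrying a label.
#' @param protected_genes gene ids never lost (e.g. designated markers).
#' @param species_names labels for the three descendant genomes.
#' @return List of class `clade_config`.
#' @export
clade_config <- function(seed = 1, n_genes = 300, n_scaffolds = 3,
                         gene_len_codons = c(80, 200),
                         spacer_len = c(50, 200),
                         branches = list(
                           A = branch_params(n_duplications = 10),
                           I = branch_params(n_inversions = 4,
                                             n_duplications = 4,
                                             n_losses = 2,
                                             te_insertions = 2),
                           B = branch_params(n_duplications = 10),
                           C = branch_params(ka = 0.09, ks = 0.30,
                                             n_inversions = 10,
                                             n_duplications = 4,
                                             n_losses = 12,
                                             te_insertions = 3)),
                         dup_target = 0.7, n_islands = 2,
                         n_te_families = 2, te_copies_per_family = 4,
                         te_len_bp = 800, rip_rounds = 2, rip_prob = 0.2,
                         category_tags = 20, category_frac = 0.5,
                         protected_genes = character(0),
                         species_names = c("A", "B", "C")) {
  stopifnot(te_len_bp >= 400 || n_te_families == 0,
            rip_prob >= 0, rip_prob <= 1,
            dup_target >= 0, dup_target <= 1,
            all(c("A", "I", "B", "C") %in% names(branches)))
  structure(list(seed = seed, n_genes = n_genes, n_scaffolds = n_scaffolds,
                 gene_len_codons = gene_len_codons, spacer_len = spacer_len,
                 branches = branches, dup_target = dup_target,
                 n_islands = n_islands, n_te_families = n_te_families,
                 te_copies_per_family = te_copies_per_family,
                 te_len_bp = te_len_bp, rip_rounds = rip_rounds,
                 rip_prob = rip_prob, category_tags = category_tags,
                 category_frac = category_frac,
                 protected_genes = protected_genes,
                 species_names = species_names),
            class = "clade_config")
}

# ---- segment-level machinery -------------------------------------------

new_segment <- function(type, id, seq, strand = "+", meta = NULL) {
  list(type = type, id = id, seq = seq, strand = strand, meta = meta)
}

#' @noRd
sim_ancestor_segments <- function(config) {
  tags <- paste0("PF", sprintf("%04d", seq_len(config$category_tags)))
  scaffolds <- vector("list", config$n_scaffolds)
  names(scaffolds) <- paste0("scf_", seq_len(config$n_scaffolds))
  gene_scaffold <- if (config$n_genes > 0)
    sort(sample.int(config$n_scaffolds, config$n_genes, replace = TRUE))
  else integer(0)
  gi <- 0L
  for (s in seq_len(config$n_scaffolds)) {
    segs <- list(new_segment("spacer", NA_character_,
                             random_biased_dna(sample(config$spacer_len[1]:config$spacer_len[2], 1))))
    for (k in seq_len(sum(gene_scaffold == s))) {
      gi <- gi + 1L
      len <- sample(config$gene_len_codons[1]:config$gene_len_codons[2], 1)
      cat_lab <- if (runif(1) < config$category_frac) sample(tags, 1) else NA_character_
      segs <- c(segs, list(
        new_segment("gene", sprintf("g%04d", gi), random_cds(len),
                    strand = sample(c("+", "-"), 1),
                    meta = list(category = cat_lab)),
        new_segment("spacer", NA_character_,
                    random_biased_dna(sample(config$spacer_len[1]:config$spacer_len[2], 1)))))
    }
    scaffolds[[s]] <- segs
  }
  list(species = "ancestor", scaffolds = scaffolds)
}

seg_gene_idx <- function(segs) {
  which(vapply(segs, function(s) s$type == "gene", logical(1)))
}

#' @noRd
assemble_annotation <- function(segG, species = segG$species) {
  rows <- list(); te_rows <- list()
  scaffolds <- character(0)
  for (sc in names(segG$scaffolds)) {
    segs <- segG$scaffolds[[sc]]
    fwd <- vapply(segs, function(s) {
      if (s$type == "gene" && s$strand == "-") reverse_complement(s$seq) else s$seq
    }, "")
    ends <- cumsum(nchar(fwd))
    starts <- ends - nchar(fwd)  # 0-based
    scaffolds[sc] <- paste(fwd, collapse = "")
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      if (s$type == "gene") {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = s$id, scaffold_id = sc, start = starts[i], end = ends[i],
          strand = s$strand, cds = s$seq, protein = translate_cds(s$seq),
          category = if (is.null(s$meta$category)) NA_character_ else s$meta$category,
          stringsAsFactors = FALSE)
      } else if (s$type == "te") {
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          copy_id = s$id, family = s$meta$family, scaffold_id = sc,
          start = starts[i], end = ends[i], strand = s$strand,
          rip_mutations = s$meta$rip_mut, stringsAsFactors = FALSE)
      }
    }
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), scaffold_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               cds = character(0), protein = character(0),
               category = character(0), stringsAsFactors = FALSE)
  ann <- genome_annotation(species, scaffolds, genes, validate = FALSE)
  attr(ann, "te_copies") <- if (length(te_rows)) do.call(rbind, te_rows) else NULL
  ann
}

#' Simulate an ancestral genome
#'
#' Random coding sequences (start codon, no internal stops, terminal stop)
#' placed in order with dinucleotide-biased intergenic spacers. Deterministic
#' under `config$seed`.
#'
#' @param config a [clade_config()].
#' @return A `genome_annotation`.
#' @export
simulate_ancestor <- function(config) {
  set.seed(config$seed)
  assemble_annotation(sim_ancestor_segments(config), species = "ancestor")
}

#' Apply RIP-type mutation to a sequence
#'
#' Per round, each CpA dinucleotide's C mutates to T with probability
#' `rip_prob`, and each TpG's G mutates to A (the reverse-strand CpA),
#' scanning a frozen copy of the sequence per round. Only C->T / G->A
#' substitutions are performed and sequence length never changes.
#'
#' @param sequence DNA string.
#' @param rounds number of RIP rounds.
#' @param rip_prob per-site mutation probability per round.
#' @return List with `seq` (mutated sequence) and `n_mutations`.
#' @export
apply_rip <- function(sequence, rounds, rip_prob) {
  v <- strsplit(sequence, "")[[1]]
  nm <- 0L
  if (length(v) >= 2L) for (r in seq_len(rounds)) {
    w <- v  # frozen copy for this round
    ca <- which(w[-length(w)] == "C" & w[-1] == "A")
    tg <- which(w[-length(w)] == "T" & w[-1] == "G")
    hit_ca <- ca[runif(length(ca)) < rip_prob]
    hit_tg <- tg[runif(length(tg)) < rip_prob]
    v[hit_ca] <- "T"
    v[hit_tg + 1L] <- "A"
    nm <- nm + length(hit_ca) + length(hit_tg)
  }
  list(seq = paste(v, collapse = ""), n_mutations = nm)
}

# Apply n_syn synonymous and n_nonsyn nonsynonymous single-base events to a
# CDS (terminal stop codon untouched). Events pick a codon weighted by its
# current number of eligible variants, then a variant uniformly; repeat hits
# at the same codon are allowed (Jukes-Cantor-style multiple substitution).
#' @noRd
mutate_cds <- function(cds, ka, ks) {
  ct <- codon_tables()
  codons <- split_codons(cds)
  L <- length(codons)
  has_stop <- ct$gc[[codons[L]]] == "*"
  mut_idx <- if (has_stop) seq_len(L - 1L) else seq_len(L)
  work <- codons[mut_idx]
  S <- sum(ct$s_sites[work])
  N <- 3 * length(work) - S
  n_syn <- rpois(1, ks * S)
  n_nonsyn <- rpois(1, ka * N)
  syn_w <- ct$syn_n[work]
  nonsyn_w <- lengths(ct$nonsyn_var[work])
  for (ev in sample(rep(c("s", "n"), c(n_syn, n_nonsyn)))) {
    if (ev == "s") {
      if (sum(syn_w) == 0) next
      i <- sample.int(length(work), 1, prob = syn_w)
      work[i] <- sample(ct$syn_var[[work[i]]], 1)
    } else {
      if (sum(nonsyn_w) == 0) next
      i <- sample.int(length(work), 1, prob = nonsyn_w)
      work[i] <- sample(ct$nonsyn_var[[work[i]]], 1)
    }
    syn_w[i] <- ct$syn_n[work[i]]
    nonsyn_w[i] <- length(ct$nonsyn_var[[work[i]]])
  }
  codons[mut_idx] <- work
  list(cds = paste(codons, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn,
       S = S, N = N)
}

#' @noRd
evolve_branch_seg <- function(segG, params, config, branch = "?") {
  truth <- list(losses = character(0),
                duplications = data.frame(new_id = character(0),
                                          source_id = character(0),
                                          island = logical(0)),
                inversions = list(), te_new = character(0),
                rates = NULL, rip = NULL)
  # 1. codon-level substitutions
  rate_rows <- list()
  for (sc in names(segG$scaffolds)) {
    segs <- segG$scaffolds[[sc]]
    for (i in seq_along(segs)) {
      if (segs[[i]]$type != "gene") next
      m <- mutate_cds(segs[[i]]$seq, params$ka, params$ks)
      segs[[i]]$seq <- m$cds
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        branch = branch, gene_id = segs[[i]]$id, n_syn = m$n_syn,
        n_nonsyn = m$n_nonsyn, S = m$S, N = m$N, stringsAsFactors = FALSE)
    }
    segG$scaffolds[[sc]] <- segs
  }
  truth$rates <- if (length(rate_rows)) do.call(rbind, rate_rows) else NULL

  all_gene_ids <- function() {
    unlist(lapply(segG$scaffolds, function(segs)
      vapply(segs[seg_gene_idx(segs)], `[[`, "", "id")), use.names = FALSE)
  }

  # 2. gene losses (uniform, excluding protected genes)
  ids <- setdiff(all_gene_ids(), config$protected_genes)
  if (params$n_losses > length(ids))
    stop("requested losses exceed available gene count")
  lost <- if (params$n_losses > 0) sample(ids, params$n_losses) else character(0)
  truth$losses <- lost
  if (length(lost)) for (sc in names(segG$scaffolds)) {
    segs <- segG$scaffolds[[sc]]
    drop <- vapply(segs, function(s) s$type == "gene" && s$id %in% lost,
                   logical(1))
    segG$scaffolds[[sc]] <- segs[!drop]
  }

  # 3. duplications: tandem, or dispersed into designated islands
  if (params$n_duplications > 0) {
    pool <- all_gene_ids()
    src <- sample(pool, params$n_duplications, replace = TRUE)
    n_island <- rbinom(1, params$n_duplications, config$dup_target)
    is_island <- sample(rep(c(TRUE, FALSE),
                            c(n_island, params$n_duplications - n_island)))
    # designated island insertion points, anchored on a gene id so the
    # island stays contiguous while other insertions shift indices
    islands <- lapply(seq_len(max(config$n_islands, 1L)), function(k) {
      sc <- sample(names(segG$scaffolds), 1)
      gidx <- seg_gene_idx(segG$scaffolds[[sc]])
      anchor <- if (length(gidx))
        sample(vapply(segG$scaffolds[[sc]][gidx], `[[`, "", "id"), 1)
      else NA_character_
      list(sc = sc, anchor = anchor)
    })
    dup_counter <- new.env(parent = emptyenv())
    for (d in seq_along(src)) {
      # locate current copy of the source gene
      found <- NULL
      for (sc in names(segG$scaffolds)) {
        segs <- segG$scaffolds[[sc]]
        gidx <- seg_gene_idx(segs)
        hit <- gidx[vapply(segs[gidx], `[[`, "", "id") == src[d]]
        if (length(hit)) { found <- list(sc = sc, i = hit[1]); break }
      }
      if (is.null(found)) next  # source itself was placed then lost; skip
      k <- (get0(src[d], envir = dup_counter, ifnotfound = 0L)) + 1L
      assign(src[d], k, envir = dup_counter)
      new_id <- paste0(src[d], ".", branch, "d", k)
      seg <- segG$scaffolds[[found$sc]][[found$i]]
      # copies diverge from their source (duplication-and-divergence);
      # with ka = ks = 0 the copy stays identical
      dup_seq <- mutate_cds(seg$seq, params$ka, params$ks)$cds
      newseg <- new_segment("gene", new_id, dup_seq, seg$strand, seg$meta)
      pad <- new_segment("spacer", NA_character_, random_biased_dna(30L))
      if (is_island[d]) {
        isl <- islands[[(d %% length(islands)) + 1L]]
        segs_i <- segG$scaffolds[[isl$sc]]
        pos <- 0L
        if (!is.na(isl$anchor)) {
          gidx <- seg_gene_idx(segs_i)
          ids <- vapply(segs_i[gidx], `[[`, "", "id")
          pos <- gidx[match(isl$anchor, ids)]
        }
        segG$scaffolds[[isl$sc]] <- append(segs_i, list(pad, newseg),
                                           after = pos)
      } else {
        segG$scaffolds[[found$sc]] <- append(segG$scaffolds[[found$sc]],
                                             list(pad, newseg),
                                             after = found$i)
      }
      truth$duplications <- rbind(truth$duplications, data.frame(
        new_id = new_id, source_id = src[d], island = is_island[d],
        stringsAsFactors = FALSE))
    }
  }

  # 4. inversions with breakpoints uniform on gene order (random breakage)
  for (inv in seq_len(params$n_inversions)) {
    counts <- vapply(segG$scaffolds, function(s) length(seg_gene_idx(s)), 0L)
    if (all(counts == 0L)) break
    sc <- sample(names(counts), 1, prob = pmax(counts, 0))
    if (counts[sc] == 0L) next
    w <- sample(params$inversion_len_genes[1]:params$inversion_len_genes[2], 1)
    w <- min(w, counts[sc])
    start_gene <- sample(seq_len(counts[sc] - w + 1L), 1)
    segs <- segG$scaffolds[[sc]]
    gidx <- seg_gene_idx(segs)
    from <- gidx[start_gene]; to <- gidx[start_gene + w - 1L]
    window <- segs[from:to]
    window <- rev(lapply(window, function(s) {
      if (s$type == "gene") {
        s$strand <- if (s$strand == "+") "-" else "+"
      } else {
        s$seq <- reverse_complement(s$seq)
        if (s$type == "te") s$strand <- if (s$strand == "+") "-" else "+"
      }
      s
    }))
    segs[from:to] <- window
    segG$scaffolds[[sc]] <- segs
    truth$inversions[[length(truth$inversions) + 1L]] <- list(
      scaffold = sc, start_gene = start_gene, n_genes = w,
      gene_ids = vapply(Filter(function(s) s$type == "gene", window),
                        `[[`, "", "id"))
  }

  # 5. new TE insertions into intergenic space
  fams <- config$te_families
  if (params$te_insertions > 0 && length(fams)) {
    for (t in seq_len(params$te_insertions)) {
      fam <- sample(names(fams), 1)
      sc <- sample(names(segG$scaffolds), 1)
      at <- sample(seq_len(length(segG$scaffolds[[sc]]) + 1L), 1)
      id <- sprintf("te_%s_%s_%d", fam, branch, t)
      segG$scaffolds[[sc]] <- append(segG$scaffolds[[sc]], list(
        new_segment("spacer", NA_character_, random_biased_dna(60L)),
        new_segment("te", id, fams[[fam]], "+",
                    meta = list(family = fam, rip_mut = 0L)),
        new_segment("spacer", NA_character_, random_biased_dna(60L))),
        after = at - 1L)
      truth$te_new <- c(truth$te_new, id)
    }
  }

  # 6. RIP acts on every TE copy present on this branch
  rip_rows <- list()
  if (config$rip_rounds > 0) for (sc in names(segG$scaffolds)) {
    segs <- segG$scaffolds[[sc]]
    for (i in seq_along(segs)) {
      if (segs[[i]]$type != "te") next
      r <- apply_rip(segs[[i]]$seq, config$rip_rounds, config$rip_prob)
      segs[[i]]$seq <- r$seq
      segs[[i]]$meta$rip_mut <- segs[[i]]$meta$rip_mut + r$n_mutations
      rip_rows[[length(rip_rows) + 1L]] <- data.frame(
        branch = branch, copy_id = segs[[i]]$id,
        family = segs[[i]]$meta$family, n_mutations = r$n_mutations,
        stringsAsFactors = FALSE)
    }
    segG$scaffolds[[sc]] <- segs
  }
  truth$rip <- if (length(rip_rows)) do.call(rbind, rip_rows) else NULL

  list(genome = segG, truth = truth)
}

#' @noRd
segments_from_annotation <- function(ann) {
  scaffolds <- vector("list", length(ann$scaffolds))
  names(scaffolds) <- names(ann$scaffolds)
  for (sc in names(ann$scaffolds)) {
    seq <- ann$scaffolds[[sc]]
    g <- ann$genes[ann$genes$scaffold_id == sc, , drop = FALSE]
    segs <- list()
    cursor <- 0L
    for (i in seq_len(nrow(g))) {
      if (g$start[i] > cursor)
        segs <- c(segs, list(new_segment("spacer", NA_character_,
                                         substr(seq, cursor + 1L, g$start[i]))))
      segs <- c(segs, list(new_segment("gene", g$gene_id[i], g$cds[i],
                                       g$strand[i],
                                       meta = list(category = g$category[i]))))
      cursor <- g$end[i]
    }
    if (cursor < nchar(seq))
      segs <- c(segs, list(new_segment("spacer", NA_character_,
                                       substr(seq, cursor + 1L, nchar(seq)))))
    scaffolds[[sc]] <- segs
  }
  list(species = ann$species, scaffolds = scaffolds)
}

#' Evolve a genome along one branch
#'
#' Applies, in order: codon-level substitutions targeting the branch's
#' (ka, ks); gene losses; tandem and island duplications; inversions with
#' breakpoints uniform on gene order; transposable-element insertions; and
#' RIP mutation of TE copies. Uses the current RNG state (seed via
#' `set.seed()` for reproducibility).
#'
#' @param genome a `genome_annotation`.
#' @param params a [branch_params()].
#' @param config a [clade_config()] supplying the shared (non-branch)
#'   parameters; `config$te_families` may carry named consensus sequences.
#' @param branch label recorded in the branch truth.
#' @return List with `genome` (evolved `genome_annotation`) and `truth`.
#' @export
evolve_branch <- function(genome, params, config = clade_config(),
                          branch = "branch") {
  segG <- segments_from_annotation(genome)
  res <- evolve_branch_seg(segG, params, config, branch = branch)
  list(genome = assemble_annotation(res$genome, species = genome$species),
       truth = res$truth)
}

#' Simulate a three-species clade with known ground truth
#'
#' Builds an ancestor, inserts ancestral TE families, then evolves:
#' ancestor -> A (basal species) and ancestor -> internal -> B and C, with
#' branch C carrying the elevated-rate parameters. TE copies inserted before
#' the split are RIP-mutated independently in each lineage, producing the
#' degenerate shared repeat families the RIP analysis expects.
#'
#' @param config a [clade_config()].
#' @return List of class `clade_simulation` with `genomes` (named list of
#'   three `genome_annotation`s) and `truth` (class `clade_truth`: ortholog
#'   map, per-branch inversion/duplication/loss registries, TE copy registry
#'   with per-copy RIP mutation counts, realized per-branch substitution
#'   counts and site totals, and the TE family consensus registry).
#' @export
simulate_clade <- function(config = clade_config()) {
  set.seed(config$seed)
  anc <- sim_ancestor_segments(config)
  ancestor_ids <- unlist(lapply(anc$scaffolds, function(segs)
    vapply(segs[seg_gene_idx(segs)], `[[`, "", "id")), use.names = FALSE)

  # ancestral TE families
  fams <- list()
  if (config$n_te_families > 0) {
    for (f in seq_len(config$n_te_families)) {
      fam_id <- sprintf("f%02d", f)
      fams[[fam_id]] <- random_biased_dna(config$te_len_bp)
      for (cp in seq_len(config$te_copies_per_family)) {
        sc <- sample(names(anc$scaffolds), 1)
        at <- sample(seq_len(length(anc$scaffolds[[sc]]) + 1L), 1)
        anc$scaffolds[[sc]] <- append(anc$scaffolds[[sc]], list(
          new_segment("spacer", NA_character_, random_biased_dna(60L)),
          new_segment("te", sprintf("te_%s_anc_%d", fam_id, cp), fams[[fam_id]],
                      "+", meta = list(family = fam_id, rip_mut = 0L)),
          new_segment("spacer", NA_character_, random_biased_dna(60L))),
          after = at - 1L)
      }
    }
  }
  config$te_families <- fams

  brA <- evolve_branch_seg(anc, config$branches$A, config, branch = "A")
  brI <- evolve_branch_seg(anc, config$branches$I, config, branch = "I")
  brB <- evolve_branch_seg(brI$genome, config$branches$B, config, branch = "B")
  brC <- evolve_branch_seg(brI$genome, config$branches$C, config, branch = "C")

  sp <- config$species_names
  genomes <- list(assemble_annotation(brA$genome, species = sp[1]),
                  assemble_annotation(brB$genome, species = sp[2]),
                  assemble_annotation(brC$genome, species = sp[3]))
  names(genomes) <- sp
  # species-prefixed gene ids so identifiers are globally unique
  for (k in seq_along(genomes)) {
    genomes[[k]]$genes$gene_id <- paste0(sp[k], "_", genomes[[k]]$genes$gene_id)
    validate_annotation(genomes[[k]])
  }

  lost <- list(A = brA$truth$losses,
               B = union(brI$truth$losses, brB$truth$losses),
               C = union(brI$truth$losses, brC$truth$losses))
  ortholog_map <- data.frame(
    ancestor = ancestor_ids,
    A = ifelse(ancestor_ids %in% lost$A, NA_character_,
               paste0(sp[1], "_", ancestor_ids)),
    B = ifelse(ancestor_ids %in% lost$B, NA_character_,
               paste0(sp[2], "_", ancestor_ids)),
    C = ifelse(ancestor_ids %in% lost$C, NA_character_,
               paste0(sp[3], "_", ancestor_ids)),
    stringsAsFactors = FALSE)
  names(ortholog_map)[2:4] <- sp

  te_registry <- do.call(rbind, Filter(Negate(is.null), lapply(
    seq_along(genomes), function(i) {
      te <- attr(genomes[[i]], "te_copies")
      if (is.null(te)) return(NULL)
      cbind(species = names(genomes)[i], te, stringsAsFactors = FALSE)
    })))

  truth <- structure(list(
    ortholog_map = ortholog_map,
    branch_truth = list(A = brA$truth, I = brI$truth, B = brB$truth,
                        C = brC$truth),
    te_registry = te_registry,
    te_families = fams,
    rates = do.call(rbind, Filter(Negate(is.null), list(
      brA$truth$rates, brI$truth$rates, brB$truth$rates, brC$truth$rates))),
    config = config), class = "clade_truth")

  structure(list(genomes = genomes, truth = truth),
            class = "clade_simulation")
}
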