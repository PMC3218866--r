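# Protein homology: all-vs-all local alignment, reciprocal best hits,
# Markov clustering into paralog families, three-way ortholog triples and
# derived summaries. Pairwise scoring uses Smith-Waterman with BLOSUM62 and
# affine gaps (open 11, extend 1), mirroring BLASTP defaults; an exact
# shared-k-mer prefilter replaces BLAST's word seeding.

#' Default homology parameters
#'
#' @param min_score minimum raw alignment score for a retained match.
#' @param kmer length of the shared amino-acid k-mer required by the
#'   prefilter before a pair is aligned (an approximation of word seeding;
#'   pairs sharing no k-mer are never scored).
#' @param gap_open,gap_extend affine gap penalties.
#' @param matrix substitution matrix name.
#' @return List of parameters.
#' @export
homology_params <- function(min_score = 50, kmer = 5, gap_open = 11,
                            gap_extend = 1, matrix = "BLOSUM62") {
  list(min_score = min_score, kmer = kmer, gap_open = gap_open,
       gap_extend = gap_extend, matrix = matrix)
}

#' Score one protein pair by local alignment
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap penalties.
#' Percent identity is identities over aligned columns (including internal
#' gap columns) times 100.
#'
#' @param protein_a,protein_b amino-acid strings.
#' @param params [homology_params()].
#' @return One-row data.frame: `score`, `pident`, `aln_len`.
#' @export
score_pair <- function(protein_a, protein_b, params = homology_params()) {
  if (nchar(protein_a) == 0L || nchar(protein_b) == 0L)
    stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  data.frame(score = Biostrings::score(aln),
             pident = Biostrings::pid(aln, type = "PID1"),
             aln_len = Biostrings::nchar(aln))
}

#' @noRd
protein_kmers <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

# candidate index pairs (i from set a, j from set b) sharing >= 1 k-mer
#' @noRd
kmer_candidates <- function(km_a, km_b) {
  idx_b <- split(rep(seq_along(km_b), lengths(km_b)), unlist(km_b))
  pairs <- vector("list", length(km_a))
  for (i in seq_along(km_a)) {
    hits <- unlist(idx_b[km_a[[i]]], use.names = FALSE)
    if (length(hits)) pairs[[i]] <- unique(hits)
  }
  pairs
}

#' All-vs-all protein similarity search
#'
#' Aligns every cross-species and within-species protein pair that passes
#' the shared-k-mer prefilter and scores at or above `min_score`.
#' Self-matches are excluded. Both ordered directions of each retained pair
#' are emitted (scores are symmetric).
#'
#' @param genomes named list of `genome_annotation`s (>= 1).
#' @param params [homology_params()].
#' @return data.frame of matches: `query_species`, `query_id`,
#'   `subject_species`, `subject_id`, `score`, `pident`, `aln_len`.
#' @export
all_vs_all <- function(genomes, params = homology_params()) {
  stopifnot(length(genomes) >= 1)
  sp <- names(genomes)
  prot <- lapply(genomes, function(g) setNames(g$genes$protein, g$genes$gene_id))
  km <- lapply(prot, protein_kmers, k = params$kmer)
  out <- list()
  for (ia in seq_along(sp)) for (ib in ia:length(sp)) {
    a <- prot[[ia]]; b <- prot[[ib]]
    if (length(a) == 0L || length(b) == 0L) next
    cand <- kmer_candidates(km[[ia]], km[[ib]])
    ii <- rep(seq_along(cand), lengths(cand))
    jj <- unlist(cand, use.names = FALSE)
    if (ia == ib) { keep <- ii < jj; ii <- ii[keep]; jj <- jj[keep] }
    if (length(ii) == 0L) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(a[ii])),
      Biostrings::AAStringSet(unname(b[jj])),
      type = "local", substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    sc <- Biostrings::score(aln)
    keep <- is.finite(params$min_score) & sc >= params$min_score
    if (!any(keep)) next
    df <- data.frame(query_species = sp[ia], query_id = names(a)[ii[keep]],
                     subject_species = sp[ib], subject_id = names(b)[jj[keep]],
                     score = sc[keep],
                     pident = Biostrings::pid(aln, type = "PID1")[keep],
                     aln_len = Biostrings::nchar(aln)[keep],
                     stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- df
    # mirror direction
    out[[length(out) + 1L]] <- data.frame(
      query_species = df$subject_species, query_id = df$subject_id,
      subject_species = df$query_species, subject_id = df$query_id,
      score = df$score, pident = df$pident, aln_len = df$aln_len,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(query_species = character(0), query_id = character(0),
                      subject_species = character(0),
                      subject_id = character(0), score = numeric(0),
                      pident = numeric(0), aln_len = integer(0)))
  res <- do.call(rbind, out)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Reciprocal best hits between two species
#'
#' A pair (g, h) is kept iff h is g's unique top-scoring hit in species B
#' and g is h's unique top-scoring hit in species A. A gene whose top score
#' is tied between two subjects is dropped from RBH entirely, protecting
#' downstream synteny anchors from arbitrary tie-breaking.
#'
#' @param matches output of [all_vs_all()] (both directions present).
#' @param species_a,species_b species labels.
#' @return data.frame `gene_a`, `gene_b`, `score`, `pident`.
#' @export
reciprocal_best_hits <- function(matches, species_a, species_b) {
  best_unique <- function(qs, ss) {
    m <- matches[matches$query_species == qs & matches$subject_species == ss, ,
                 drop = FALSE]
    if (nrow(m) == 0L)
      return(data.frame(q = character(0), s = character(0),
                        score = numeric(0), pident = numeric(0)))
    res <- lapply(split(m, m$query_id), function(d) {
      top <- max(d$score)
      hit <- d[d$score == top, , drop = FALSE]
      if (nrow(hit) != 1L) return(NULL)  # tie -> drop gene
      data.frame(q = hit$query_id, s = hit$subject_id, score = hit$score,
                 pident = hit$pident, stringsAsFactors = FALSE)
    })
    do.call(rbind, Filter(Negate(is.null), res))
  }
  ab <- best_unique(species_a, species_b)
  ba <- best_unique(species_b, species_a)
  if (is.null(ab) || is.null(ba) || nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), pident = numeric(0)))
  key_ab <- paste(ab$q, ab$s); key_ba <- paste(ba$s, ba$q)
  keep <- ab[key_ab %in% key_ba, , drop = FALSE]
  res <- data.frame(gene_a = keep$q, gene_b = keep$s, score = keep$score,
                    pident = keep$pident, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$gene_a), , drop = FALSE]
}

#' Build an undirected similarity graph from matches
#'
#' Nodes are `species|gene_id`; edge weight is the maximum score seen in
#' either direction. Used as the Markov clustering substrate.
#'
#' @param matches output of [all_vs_all()].
#' @return data.frame `from`, `to`, `weight`.
#' @export
similarity_graph <- function(matches) {
  if (nrow(matches) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  a <- paste0(matches$query_species, "|", matches$query_id)
  b <- paste0(matches$subject_species, "|", matches$subject_id)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  w <- tapply(matches$score, key, max)
  parts <- strsplit(names(w), " ", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             to = vapply(parts, `[`, "", 2),
             weight = as.numeric(w), stringsAsFactors = FALSE)
}

#' Markov clustering of a weighted similarity graph
#'
#' Column-normalizes the (self-loop augmented) adjacency matrix, then
#' alternates expansion (matrix squaring) and inflation (entrywise power
#' followed by renormalization) until the maximum entry change is below
#' `tol` or `max_iter` iterations. Clusters are read from attractor rows.
#' Self-loops are set to each node's maximum incident weight.
#'
#' @param graph data.frame `from`, `to`, `weight` (positive), or a list of
#'   node names for singleton handling.
#' @param inflation inflation exponent (> 1, default 2).
#' @param nodes optional full node set (isolated nodes become singletons).
#' @param tol,max_iter convergence controls.
#' @param prune entries below this are zeroed each iteration (sparsity).
#' @return data.frame `family_id`, `member` (one row per node).
#' @export
mcl_cluster <- function(graph, inflation = 2, nodes = NULL, tol = 1e-6,
                        max_iter = 100, prune = 1e-8) {
  stopifnot(inflation > 1)
  if (nrow(graph) > 0 && any(graph$weight <= 0))
    stop("non-positive edge weights")
  nodes <- sort(unique(c(nodes, graph$from, graph$to)))
  n <- length(nodes)
  if (n == 0L)
    return(data.frame(family_id = character(0), member = character(0)))
  i <- match(graph$from, nodes); j <- match(graph$to, nodes)
  M <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(graph$weight, 2), dims = c(n, n),
                            use.last.ij = TRUE)
  loop <- apply(M, 1, max)
  loop[loop == 0] <- 1
  Matrix::diag(M) <- loop
  norm_cols <- function(m) {
    cs <- Matrix::colSums(m)
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- norm_cols(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2@x <- M2@x^inflation             # inflation
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- norm_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  # attractors: rows with nonzero diagonal; cluster = nonzero cols of row
  dm <- Matrix::diag(M)
  attractors <- which(dm > tol)
  assigned <- rep(NA_integer_, n)
  fam <- 0L
  for (a in attractors) {
    members <- which(M[a, ] > tol)
    members <- members[is.na(assigned[members])]
    if (!length(members)) next
    if (!is.na(assigned[a])) { assigned[members] <- assigned[a]; next }
    fam <- fam + 1L
    assigned[c(a, members)] <- fam
  }
  for (k in which(is.na(assigned))) { fam <- fam + 1L; assigned[k] <- fam }
  data.frame(family_id = sprintf("fam%04d", assigned), member = nodes,
             stringsAsFactors = FALSE)
}

#' Three-way ortholog triples as closed RBH triangles
#'
#' A triple (a, b, c) is reported iff (a,b), (b,c) and (a,c) are each
#' reciprocal best hits.
#'
#' @param rbh_ab,rbh_bc,rbh_ac outputs of [reciprocal_best_hits()] for the
#'   species pairs (A,B), (B,C) and (A,C).
#' @return data.frame `gene_a`, `gene_b`, `gene_c`.
#' @export
three_way_orthologs <- function(rbh_ab, rbh_bc, rbh_ac) {
  m <- merge(rbh_ab[, c("gene_a", "gene_b")],
             rbh_bc[, c("gene_a", "gene_b")],
             by.x = "gene_b", by.y = "gene_a")
  names(m) <- c("gene_b", "gene_a", "gene_c")
  key_ac <- paste(rbh_ac$gene_a, rbh_ac$gene_b)
  m <- m[paste(m$gene_a, m$gene_c) %in% key_ac, c("gene_a", "gene_b", "gene_c")]
  rownames(m) <- NULL
  m[order(m$gene_a), , drop = FALSE]
}

#' Venn partition of genes across the three species
#'
#' Each gene lands in exactly one cell: `core` (member of an ortholog
#' triple), a pairwise-only cell (in RBH for one species pair but in no
#' triple), or `unique` (no cross-species RBH).
#'
#' @param genomes named list of three `genome_annotation`s.
#' @param triples output of [three_way_orthologs()].
#' @param rbh named list with elements `AB`, `BC`, `AC` of RBH tables.
#' @return List with `counts` (named numeric: core, AB_only, AC_only,
#'   BC_only, unique_A, unique_B, unique_C) and `assignment` (per-gene
#'   data.frame `species`, `gene_id`, `cell`).
#' @export
orthology_partition <- function(genomes, triples, rbh) {
  sp <- names(genomes)
  cells <- list()
  for (k in 1:3) {
    ids <- genomes[[k]]$genes$gene_id
    in_triple <- ids %in% triples[[c("gene_a", "gene_b", "gene_c")[k]]]
    in_ab <- ids %in% (if (k == 1) rbh$AB$gene_a else if (k == 2) rbh$AB$gene_b else character(0))
    in_ac <- ids %in% (if (k == 1) rbh$AC$gene_a else if (k == 3) rbh$AC$gene_b else character(0))
    in_bc <- ids %in% (if (k == 2) rbh$BC$gene_a else if (k == 3) rbh$BC$gene_b else character(0))
    cell <- ifelse(in_triple, "core",
            ifelse(in_ab, "AB_only",
            ifelse(in_ac, "AC_only",
            ifelse(in_bc, "BC_only", paste0("unique_", c("A", "B", "C")[k])))))
    cells[[k]] <- data.frame(species = sp[k], gene_id = ids, cell = cell,
                             stringsAsFactors = FALSE)
  }
  assignment <- do.call(rbind, cells)
  lv <- c("core", "AB_only", "AC_only", "BC_only",
          "unique_A", "unique_B", "unique_C")
  counts <- table(factor(assignment$cell, levels = lv))
  # core counted once per triple, not per gene
  counts["core"] <- nrow(triples)
  pair_cells <- c("AB_only", "AC_only", "BC_only")
  counts[pair_cells] <- counts[pair_cells] / 2  # two genes per pair link
  list(counts = c(counts), assignment = assignment)
}

#' Families expanded since the most recent common ancestor
#'
#' Removes ortholog-triple members from each paralog family and reports the
#' per-species residual counts; a family is flagged `expanded` when both
#' designated species retain strictly more residual members than the
#' reference species.
#'
#' @param families output of [mcl_cluster()] on `species|gene` node names.
#' @param triples output of [three_way_orthologs()].
#' @param species all three species labels, `c(A, B, C)`.
#' @param expanded_in the two species tested jointly (default B-like pair:
#'   the first two labels).
#' @return data.frame per family: residual counts per species, total, and
#'   `expanded` flag; sorted by total residual, decreasing.
#' @export
expanded_families <- function(families, triples, species,
                              expanded_in = species[1:2]) {
  parts <- strsplit(families$member, "|", fixed = TRUE)
  fam <- data.frame(family_id = families$family_id,
                    species = vapply(parts, `[`, "", 1),
                    gene_id = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  ortho <- c(triples$gene_a, triples$gene_b, triples$gene_c)
  ortho_sp <- rep(species, each = nrow(triples))
  fam$is_ortho <- paste(fam$species, fam$gene_id) %in% paste(ortho_sp, ortho)
  resid <- fam[!fam$is_ortho, , drop = FALSE]
  out <- lapply(unique(fam$family_id), function(fid) {
    d <- resid[resid$family_id == fid, , drop = FALSE]
    cnt <- table(factor(d$species, levels = species))
    data.frame(family_id = fid, t(as.integer(cnt)),
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(family_id = character(0)))
  res <- do.call(rbind, out)
  names(res)[-1] <- species
  res$total <- rowSums(res[, species, drop = FALSE])
  other <- setdiff(species, expanded_in)
  res$expanded <- res[[expanded_in[1]]] > res[[other]] &
    res[[expanded_in[2]]] > res[[other]]
  res <- res[order(-res$total), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select phylogenomic marker triples
#'
#' A seeded random sample of ortholog triples whose members are syntenic in
#' every genome and are "true orthologs": no non-orthologous within- or
#' cross-species match with percent identity above `similarity_cutoff`.
#'
#' @param triples output of [three_way_orthologs()].
#' @param classification data.frame `species`, `gene_id`, `class` with
#'   `syntenic` / `non_syntenic` (see [classify_genes()]).
#' @param matches output of [all_vs_all()].
#' @param n markers to sample.
#' @param similarity_cutoff percent identity above which a non-orthologous
#'   match disqualifies a triple (default 50).
#' @param seed RNG seed for the sample.
#' @return data.frame of `n` selected triples.
#' @export
select_phylogenomic_markers <- function(triples, classification, matches,
                                        n, similarity_cutoff = 50,
                                        seed = 1) {
  if (nrow(triples) == 0L) stop("no ortholog triples available")
  synt <- classification$gene_id[classification$class == "syntenic"]
  all_synt <- triples$gene_a %in% synt & triples$gene_b %in% synt &
    triples$gene_c %in% synt
  # matches between genes of the same triple are the orthologous ones
  tri_of <- c(setNames(seq_len(nrow(triples)), triples$gene_a),
              setNames(seq_len(nrow(triples)), triples$gene_b),
              setNames(seq_len(nrow(triples)), triples$gene_c))
  mt_q <- tri_of[matches$query_id]
  mt_s <- tri_of[matches$subject_id]
  non_ortho <- matches[(is.na(mt_q) | is.na(mt_s) | mt_q != mt_s) &
                         matches$pident > similarity_cutoff, , drop = FALSE]
  tainted <- unique(c(non_ortho$query_id, non_ortho$subject_id))
  clean <- all_synt & !(triples$gene_a %in% tainted) &
    !(triples$gene_b %in% tainted) & !(triples$gene_c %in% tainted)
  eligible <- triples[clean, , drop = FALSE]
  if (nrow(eligible) < n)
    stop("only ", nrow(eligible), " eligible markers, need ", n)
  set.seed(seed)
  sel <- eligible[sample.int(nrow(eligible), n), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Mean percent identity of syntenic ortholog pairs
#'
#' @param rbh RBH table for one species pair (with `pident`).
#' @param classification classification table covering both species.
#' @return Arithmetic mean percent identity over pairs whose two members
#'   are both syntenic.
#' @export
mean_syntenic_identity <- function(rbh, classification) {
  synt <- classification$gene_id[classification$class == "syntenic"]
  keep <- rbh$gene_a %in% synt & rbh$gene_b %in% synt
  if (!any(keep)) stop("no syntenic ortholog pairs")
  mean(rbh$pident[keep])
}
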