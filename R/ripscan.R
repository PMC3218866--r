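# RIP (repeat-induced point mutation) analysis: Margolin dinucleotide
# indices at sequence, family and genome scope; a minimal seed-and-extend
# de novo repeat-family finder; transition/transversion ratios on
# alignments. Counts are forward-strand only by default (the convention the
# printed index thresholds assume); the composite index (CA+TG)/(AC+GT) is
# already strand-symmetrized. A both-strands mode is available.

DINUCS <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                 rep(c("A", "C", "G", "T"), 4))

#' Overlapping dinucleotide counts
#'
#' Counts the 16 dinucleotides over overlapping windows on the forward
#' strand. Windows containing a non-ACGT letter are skipped (and tallied).
#' Multi-sequence input sums counts across sequences -- the family-scope
#' mode used to index short degenerate repeat copies jointly.
#'
#' @param sequences character vector of DNA sequences (N allowed).
#' @param both_strands also count the reverse complement (default FALSE).
#' @return List of class `dinuc_counts`: `counts` (named integer, 16
#'   dinucleotides), `total_windows`, `skipped`.
#' @export
dinucleotide_counts <- function(sequences, both_strands = FALSE) {
  sequences <- sequences[nchar(sequences) > 0L]
  if (!length(sequences)) {
    cnt <- setNames(integer(16), DINUCS)
    return(structure(list(counts = cnt, total_windows = 0L, skipped = 0L),
                     class = "dinuc_counts"))
  }
  set <- Biostrings::DNAStringSet(sequences)
  if (both_strands) set <- c(set, Biostrings::reverseComplement(set))
  m <- Biostrings::dinucleotideFrequency(set, step = 1)
  cnt <- colSums(m)[DINUCS]
  total <- sum(pmax(Biostrings::width(set) - 1L, 0L))
  structure(list(counts = as.integer(cnt) |> setNames(DINUCS),
                 total_windows = as.integer(total),
                 skipped = as.integer(total - sum(cnt))),
            class = "dinuc_counts")
}

#' RIP indices from dinucleotide counts
#'
#' `ta_at` = TA/AT and `composite` = (CA+TG)/(AC+GT). A sequence is called
#' `rip_positive` iff TA/AT exceeds `ta_at_min` and the composite falls
#' below `composite_max` (defaults 0.89 and 1.03, the conventional
#' thresholds). A zero denominator leaves the ratio undefined and the
#' verdict `indeterminate`.
#'
#' @param counts a `dinuc_counts` (or named count vector).
#' @param ta_at_min,composite_max classification thresholds.
#' @return List of class `rip_indices`: `ta_at`, `composite`, `verdict`,
#'   `thresholds`.
#' @export
rip_indices <- function(counts, ta_at_min = 0.89, composite_max = 1.03) {
  cnt <- if (inherits(counts, "dinuc_counts")) counts$counts else counts
  ta_at <- if (cnt[["AT"]] == 0) NA_real_ else cnt[["TA"]] / cnt[["AT"]]
  den <- cnt[["AC"]] + cnt[["GT"]]
  composite <- if (den == 0) NA_real_ else (cnt[["CA"]] + cnt[["TG"]]) / den
  verdict <- if (is.na(ta_at) || is.na(composite)) "indeterminate"
  else if (ta_at > ta_at_min && composite < composite_max) "rip_positive"
  else "rip_negative"
  structure(list(ta_at = ta_at, composite = composite, verdict = verdict,
                 thresholds = c(ta_at_min = ta_at_min,
                                composite_max = composite_max)),
            class = "rip_indices")
}

#' @export
print.rip_indices <- function(x, ...) {
  cat(sprintf("<rip_indices> TA/AT = %.3f, (CA+TG)/(AC+GT) = %.3f -> %s\n",
              x$ta_at, x$composite, x$verdict))
  invisible(x)
}

#' Genome-wide RIP profile
#'
#' Whole-genome summed dinucleotide counts give one pair of indices; a
#' sliding window (default 1 kb, step 500 b) gives a per-window track.
#'
#' @param genome a `genome_annotation`.
#' @param window,step window size and step in bp.
#' @return List: `genome_wide` (a `rip_indices`), `track` (data.frame
#'   `scaffold_id`, `start` (0-based), `end`, `ta_at`, `composite`).
#' @export
genome_rip_profile <- function(genome, window = 1000, step = 500) {
  gw <- rip_indices(dinucleotide_counts(unname(genome$scaffolds)))
  rows <- list()
  for (sc in names(genome$scaffolds)) {
    L <- nchar(genome$scaffolds[[sc]])
    if (L < window) next
    starts <- seq(0L, L - window, by = step)
    wins <- substring(genome$scaffolds[[sc]], starts + 1L, starts + window)
    idx <- lapply(wins, function(w) rip_indices(dinucleotide_counts(w)))
    rows[[sc]] <- data.frame(
      scaffold_id = sc, start = starts, end = starts + window,
      ta_at = vapply(idx, `[[`, 0, "ta_at"),
      composite = vapply(idx, `[[`, 0, "composite"),
      stringsAsFactors = FALSE)
  }
  track <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_id = character(0), start = integer(0),
               end = integer(0), ta_at = numeric(0), composite = numeric(0))
  rownames(track) <- NULL
  list(genome_wide = gw, track = track)
}

#' RIP indices for repeat families
#'
#' Sums dinucleotide counts over all copies of each family (the family-sum
#' rule for short degenerate copies), then computes one `rip_indices` per
#' family.
#'
#' @param genome a `genome_annotation`.
#' @param families output of [find_repeat_families()] (or any data.frame
#'   `family_id`, `scaffold_id`, `start`, `end`).
#' @return data.frame, one row per family: copy count, summed length,
#'   `ta_at`, `composite`, `verdict`.
#' @export
family_rip_indices <- function(genome, families) {
  out <- lapply(split(families, families$family_id), function(fam) {
    seqs <- substring(genome$scaffolds[fam$scaffold_id], fam$start + 1L,
                      fam$end)
    ri <- rip_indices(dinucleotide_counts(seqs))
    data.frame(family_id = fam$family_id[1], n_copies = nrow(fam),
               total_bp = sum(fam$end - fam$start), ta_at = ri$ta_at,
               composite = ri$composite, verdict = ri$verdict,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# merge overlapping / adjacent intervals on one scaffold
#' @noRd
merge_intervals <- function(start, end, slack = 0L) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + slack) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' De novo repeat-family detection
#'
#' A deliberately minimal seed-and-extend finder for the classic repeat
#' criteria (length >= 400 bp, identity > 92%, >= 3 copies): k-mers
#' occurring more than once (on either strand) are merged into candidate
#' intervals of at least `min_len`; candidates are clustered by
#' single-linkage on global-alignment percent identity (the better of the
#' two orientations), and clusters with at least `min_copies` copies are
#' reported. Validated on synthetic genomes; not a substitute for a
#' production repeat annotator on real data.
#'
#' @param genome a `genome_annotation`.
#' @param min_len minimum copy length in bp (default 400).
#' @param min_identity minimum pairwise identity within a family (default
#'   0.92).
#' @param min_copies minimum copies per family (default 3).
#' @param k seed k-mer length (default 12; long enough that chance
#'   three-fold k-mer repeats never reach `min_len` after merging, short
#'   enough that exact seeds stay dense across independently degraded
#'   copies).
#' @return data.frame, one row per copy: `family_id`, `copy_id`,
#'   `scaffold_id`, `start` (0-based), `end`, `strand`.
#' @export
find_repeat_families <- function(genome, min_len = 400, min_identity = 0.92,
                                 min_copies = 3, k = 12) {
  empty <- data.frame(family_id = character(0), copy_id = character(0),
                      scaffold_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  scafs <- genome$scaffolds
  if (!length(scafs)) return(empty)
  # k-mer occurrence tally over both strands in forward coordinates; each
  # copy of a repeat contributes its canonical-orientation k-mers exactly
  # once, so a k-mer seen >= min_copies times seeds a candidate region
  kv <- character(0); sc_v <- character(0); pos_v <- integer(0)
  for (sc in names(scafs)) {
    s <- scafs[[sc]]
    L <- nchar(s)
    if (L < k) next
    np <- L - k + 1L
    fwd <- substring(s, 1:np, k:L)
    rcs <- reverse_complement(s)
    rev <- substring(rcs, 1:np, k:L)
    kv <- c(kv, fwd, rev)
    sc_v <- c(sc_v, rep(sc, 2L * np))
    pos_v <- c(pos_v, 1:np, np:1)  # rc k-mer at p starts at fwd pos np-p+1
  }
  if (!length(kv)) return(empty)
  # seed on pairs: requiring all min_copies copies to share an exact
  # k-mer is too strict once copies have degraded independently; the
  # copy-number criterion is enforced at the clustering stage
  keep <- kv %in% unique(kv[duplicated(kv)])
  if (!any(keep)) return(empty)
  cov <- data.frame(sc = sc_v[keep], start = pos_v[keep] - 1L,
                    end = pos_v[keep] - 1L + k, stringsAsFactors = FALSE)
  cands <- list()
  for (sc in unique(cov$sc)) {
    d <- cov[cov$sc == sc, ]
    mi <- merge_intervals(d$start, d$end, slack = 2L * k)
    mi <- mi[mi$end - mi$start >= min_len, , drop = FALSE]
    if (nrow(mi)) cands[[sc]] <- data.frame(scaffold_id = sc, mi)
  }
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  n <- nrow(cands)
  if (n < min_copies) return(empty)
  seqs <- substring(scafs[cands$scaffold_id], cands$start + 1L, cands$end)
  # single-linkage clustering on best-orientation identity; candidates are
  # fragments of differing extents, so end gaps are free (overlap
  # alignment) and a minimum aligned span guards against trivial overlaps
  pair_id <- function(x, y) {
    span_min <- 0.6 * min(nchar(x), nchar(y))
    best <- 0
    for (yy in c(y, reverse_complement(y))) {
      a <- Biostrings::pairwiseAlignment(x, yy, type = "overlap")
      if (Biostrings::nchar(a) >= span_min)
        best <- max(best, Biostrings::pid(a, type = "PID1") / 100)
    }
    best
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (find(i) == find(j)) next
    if (pair_id(seqs[i], seqs[j]) >= min_identity)
      parent[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, 0L)
  keep_roots <- as.integer(names(which(table(root) >= min_copies)))
  if (!length(keep_roots)) return(empty)
  rows <- list()
  fam_i <- 0L
  for (r in keep_roots) {
    fam_i <- fam_i + 1L
    members <- which(root == r)
    rows[[fam_i]] <- data.frame(
      family_id = sprintf("repfam%02d", fam_i),
      copy_id = sprintf("repfam%02d_c%d", fam_i, seq_along(members)),
      scaffold_id = cands$scaffold_id[members],
      start = cands$start[members], end = cands$end[members],
      strand = "+", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Transition/transversion ratio of a multiple alignment
#'
#' Counts transitions (A<->G, C<->T) and transversions over all sequence
#' pairs and all columns where neither sequence is gapped. `Inf` with a
#' flag when no transversion is observed (the RIP-only signature); `NaN`
#' flagged undefined when there are no differences at all.
#'
#' @param msa character vector of >= 2 aligned, equal-length sequences.
#' @return List: `transitions`, `transversions`, `ratio`, `flag`
#'   (`ok`, `infinite`, `undefined`).
#' @export
alignment_ti_tv <- function(msa) {
  stopifnot(length(msa) >= 2)
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  ti <- 0L; tv <- 0L
  for (i in seq_len(nrow(mat) - 1L)) for (j in (i + 1L):nrow(mat)) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- a %in% c(purines, pyrimidines) & b %in% c(purines, pyrimidines)
    diff <- ok & a != b
    is_ti <- diff & ((a %in% purines & b %in% purines) |
                       (a %in% pyrimidines & b %in% pyrimidines))
    ti <- ti + sum(is_ti)
    tv <- tv + sum(diff & !is_ti)
  }
  flag <- if (ti + tv == 0L) "undefined" else if (tv == 0L) "infinite" else "ok"
  list(transitions = ti, transversions = tv,
       ratio = if (flag == "undefined") NaN else ti / tv, flag = flag)
}

#' Curate repeat-family copies for index analysis
#'
#' Ranks copies by mean pairwise identity to the other copies and keeps the
#' top `q` fraction -- a heuristic stand-in for manually selecting the most
#' recent, least degenerate insertions before recomputing indices.
#'
#' @param seqs character vector of copy sequences (>= 2).
#' @param q fraction of copies kept (default 0.5, at least 2).
#' @return Character vector of the retained sequences.
#' @export
curate_family_copies <- function(seqs, q = 0.5) {
  n <- length(seqs)
  stopifnot(n >= 2)
  idm <- matrix(100, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "global")
    idm[i, j] <- idm[j, i] <- Biostrings::pid(a, type = "PID1")
  }
  mean_id <- rowMeans(idm) - 100 / n  # drop self-contribution
  keep <- order(-mean_id)[seq_len(max(2L, ceiling(q * n)))]
  seqs[sort(keep)]
}
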