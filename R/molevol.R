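# Codon-level evolutionary rates and codon usage. Ka/Ks follows
# Nei & Gojobori (1986): mutational-opportunity site counting, averaging of
# synonymous/nonsynonymous difference counts over all shortest pathways
# (stop-codon pathways excluded), and Jukes-Cantor correction
# d = -3/4 log(1 - 4p/3).

#' Align two proteins globally
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine 11/1), returning the
#' two gapped strings used for codon back-translation.
#'
#' @param protein_a,protein_b amino-acid strings.
#' @return Character vector of length 2 (aligned a, aligned b).
#' @export
protein_align <- function(protein_a, protein_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

#' Back-translate a protein alignment to paired codons
#'
#' Verifies that each protein is the translation of its CDS (terminal stop
#' codons are stripped first), back-translates the alignment to codons and
#' drops columns gapped in either sequence.
#'
#' @param aln_a,aln_b aligned (gapped) protein strings.
#' @param cds_a,cds_b the corresponding coding sequences.
#' @return List with `codons_a`, `codons_b` (equal-length codon vectors).
#' @export
codon_align <- function(aln_a, aln_b, cds_a, cds_b) {
  strip_stop <- function(cds) {
    cods <- split_codons(cds)
    if (codon_tables()$gc[[cods[length(cods)]]] == "*")
      cods <- cods[-length(cods)]
    cods
  }
  ca <- strip_stop(cds_a); cb <- strip_stop(cds_b)
  ua <- gsub("-", "", aln_a); ub <- gsub("-", "", aln_b)
  if (paste(vapply(ca, function(x) codon_tables()$gc[[x]], ""), collapse = "") != ua ||
      paste(vapply(cb, function(x) codon_tables()$gc[[x]], ""), collapse = "") != ub)
    stop("protein alignment does not match CDS translation")
  va <- strsplit(aln_a, "")[[1]]
  vb <- strsplit(aln_b, "")[[1]]
  ia <- cumsum(va != "-"); ib <- cumsum(vb != "-")
  keep <- va != "-" & vb != "-"
  list(codons_a = ca[ia[keep]], codons_b = cb[ib[keep]])
}

#' Nei-Gojobori (1986) Ka/Ks for paired codons
#'
#' Synonymous sites are counted by mutational fraction (stop-producing
#' changes count as nonsynonymous); differences in multi-substitution
#' codons are averaged over all shortest pathways with equal weights,
#' excluding pathways through stop codons; proportions are Jukes-Cantor
#' corrected. Proportions at or beyond the correction's domain (p >= 3/4)
#' are flagged saturated with the rate undefined.
#'
#' @param codons_a,codons_b equal-length sense-codon vectors (e.g. from
#'   [codon_align()]).
#' @return List of class `codon_pair_stats`: `S`, `N`, `sd`, `nd`, `ps`,
#'   `pn`, `Ks`, `Ka`, `ka_ks`, `saturated_s`, `saturated_n`.
#' @export
ng86 <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b), length(codons_a) >= 1)
  ct <- codon_tables()
  if (any(!codons_a %in% ct$sense) || any(!codons_b %in% ct$sense))
    stop("stop codon in input")
  ngt <- ng86_pair_tables()
  S <- (sum(ct$s_sites[codons_a]) + sum(ct$s_sites[codons_b])) / 2
  N <- 3 * length(codons_a) - S
  sd <- sum(ngt$SD[cbind(codons_a, codons_b)])
  nd <- sum(ngt$ND[cbind(codons_a, codons_b)])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  structure(list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka,
                 ka_ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks
                         else NA_real_,
                 saturated_s = ps >= 0.75, saturated_n = pn >= 0.75),
            class = "codon_pair_stats")
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: translate, align globally, back-translate, run
#' [ng86()].
#'
#' @param cds_a,cds_b coding sequences.
#' @return A `codon_pair_stats`.
#' @export
ka_ks_pair <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  aln <- protein_align(pa, pb)
  cp <- codon_align(aln[1], aln[2], cds_a, cds_b)
  ng86(cp$codons_a, cp$codons_b)
}

#' Compare two sets of evolutionary rates
#'
#' Medians plus the two-tailed Wilcoxon rank-sum p-value: exact
#' enumeration when the combined sample size is at most 20 and there are no
#' ties, normal approximation with tie correction otherwise.
#'
#' @param rates_1,rates_2 numeric vectors (NA dropped).
#' @return List: `median_1`, `median_2`, `p_value`, `method`.
#' @export
rate_set_comparison <- function(rates_1, rates_2) {
  x <- rates_1[!is.na(rates_1)]; y <- rates_2[!is.na(rates_2)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = !exact))
  list(median_1 = median(x), median_2 = median(y),
       p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Codon usage table and relative adaptiveness
#'
#' Codon frequencies within each synonymous family and the relative
#' adaptiveness w(codon) = freq / freq(most frequent synonym). Codons never
#' observed receive the pseudo-adaptiveness 0.5 / max_count of their family
#' (so CAI never hits log 0); terminal stop codons are ignored.
#'
#' @param cds character vector of coding sequences.
#' @return data.frame: `codon`, `aa`, `count`, `freq` (within synonym
#'   family), `w`.
#' @export
codon_usage_table <- function(cds) {
  stopifnot(length(cds) >= 1)
  ct <- codon_tables()
  cods <- unlist(lapply(cds, split_codons), use.names = FALSE)
  cods <- cods[cods %in% ct$sense]
  cnt <- table(factor(cods, levels = ct$sense))
  res <- data.frame(codon = ct$sense,
                    aa = vapply(ct$sense, function(x) ct$gc[[x]], ""),
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  parts <- split(seq_len(nrow(res)), res$aa)
  res$freq <- NA_real_; res$w <- NA_real_
  for (idx in parts) {
    tot <- sum(res$count[idx])
    mx <- max(res$count[idx])
    res$freq[idx] <- if (tot > 0) res$count[idx] / tot else 1 / length(idx)
    res$w[idx] <- if (mx > 0) ifelse(res$count[idx] == 0, 0.5 / mx,
                                     res$count[idx] / mx)
                  else 1
  }
  rownames(res) <- NULL
  res
}

#' Codon adaptation index of one gene
#'
#' Geometric mean (computed in log space) of the relative adaptiveness of
#' the gene's codons, excluding the singleton codons ATG and TGG and any
#' stop codon.
#'
#' @param cds coding sequence.
#' @param w_table output of [codon_usage_table()].
#' @param exclude codons excluded from the mean (default ATG, TGG).
#' @return List of class `cai_result`: `cai`, `n_codons`.
#' @export
cai <- function(cds, w_table, exclude = c("ATG", "TGG")) {
  ct <- codon_tables()
  cods <- split_codons(cds)
  cods <- cods[cods %in% ct$sense & !cods %in% exclude]
  if (!length(cods)) stop("gene consists only of excluded codons")
  w <- w_table$w[match(cods, w_table$codon)]
  structure(list(cai = exp(mean(log(w))), n_codons = length(cods)),
            class = "cai_result")
}

#' Compare codon usage between syntenic and non-syntenic genes
#'
#' Builds the reference codon-usage table from a reference gene set
#' (default: the syntenic genes), computes the CAI of every gene, and
#' compares the syntenic and non-syntenic CAI distributions with the
#' two-tailed Wilcoxon rank-sum test. Similar distributions (large p,
#' similar medians) indicate the non-syntenic genes share the core
#' genome's codon usage.
#'
#' @param genome a `genome_annotation`.
#' @param classification classification of this genome's genes
#'   ([classify_genes()]).
#' @param reference_ids genes used for the reference usage table (default:
#'   all syntenic genes).
#' @return List: `cai` (per-gene data.frame), `comparison`
#'   ([rate_set_comparison()] result or NULL), `degenerate` flag.
#' @export
compare_region_codon_usage <- function(genome, classification,
                                       reference_ids = NULL) {
  cls <- classification[match(genome$genes$gene_id, classification$gene_id), ]
  if (is.null(reference_ids))
    reference_ids <- cls$gene_id[cls$class == "syntenic"]
  if (!length(reference_ids)) stop("empty reference set")
  ref_cds <- genome$genes$cds[genome$genes$gene_id %in% reference_ids]
  wt <- codon_usage_table(ref_cds)
  cai_all <- vapply(genome$genes$cds, function(x) cai(x, wt)$cai, 0,
                    USE.NAMES = FALSE)
  df <- data.frame(gene_id = genome$genes$gene_id, class = cls$class,
                   cai = cai_all, stringsAsFactors = FALSE)
  synt <- df$cai[df$class == "syntenic"]
  nons <- df$cai[df$class == "non_syntenic"]
  degenerate <- length(synt) == 0 || length(nons) == 0
  cmp <- if (!degenerate) rate_set_comparison(synt, nons) else NULL
  list(cai = df, comparison = cmp, degenerate = degenerate)
}

#' Concatenated-marker Ka/Ks
#'
#' Concatenates the codon alignments of a set of marker gene pairs and runs
#' one [ng86()] on the concatenation (the genome-scale mode in which rate
#' medians are computed over a fixed marker panel).
#'
#' @param cds_pairs list of two-element character vectors `(cds_a, cds_b)`.
#' @return A `codon_pair_stats` on the concatenated alignment.
#' @export
concatenated_ka_ks <- function(cds_pairs) {
  ca <- character(0); cb <- character(0)
  for (p in cds_pairs) {
    aln <- protein_align(translate_cds(p[1]), translate_cds(p[2]))
    cp <- codon_align(aln[1], aln[2], p[1], p[2])
    ca <- c(ca, cp$codons_a); cb <- c(cb, cp$codons_b)
  }
  ng86(ca, cb)
}
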