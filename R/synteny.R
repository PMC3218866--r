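# Ortholog-anchored synteny: greedy chaining of anchors into blocks per
# scaffold pair, per-gene syntenic/non-syntenic classification using the
# three-consecutive-gene break rule, a gene-order permutation null, and
# contingency-table enrichment tests on non-syntenic regions.

#' Synteny chaining parameters
#'
#' @param min_genes minimum anchors per block (>= 2, default 3).
#' @param max_gap maximum consecutive non-anchor genes tolerated inside a
#'   block on either genome (default 2 = `break_run` - 1).
#' @param min_density minimum anchors / genes spanned on the reference
#'   genome (default 0.5).
#' @param break_run run of consecutive unanchored genes declaring a break
#'   in synteny (default 3).
#' @return List of class `synteny_params`.
#' @export
synteny_params <- function(min_genes = 3, max_gap = 2, min_density = 0.5,
                           break_run = 3) {
  stopifnot(min_genes >= 2, max_gap >= 0, break_run >= 1)
  structure(list(min_genes = min_genes, max_gap = max_gap,
                 min_density = min_density, break_run = break_run),
            class = "synteny_params")
}

# anchors joined to both gene orders; one row per anchor with positions
#' @noRd
anchor_positions <- function(order_a, order_b, anchors) {
  ia <- match(anchors$gene_a, order_a$gene_id)
  ib <- match(anchors$gene_b, order_b$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("anchor gene absent from gene order")
  data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
             scaf_a = order_a$scaffold_id[ia], pos_a = order_a$position[ia],
             scaf_b = order_b$scaffold_id[ib], pos_b = order_b$position[ib],
             stringsAsFactors = FALSE)
}

#' Build synteny blocks by greedy anchor chaining
#'
#' Scans genome A's gene order; the current chain is extended while the
#' next anchor shares the scaffold pair, continues the chain's orientation
#' on genome B, and leaves gaps of at most `max_gap` genes on both genomes.
#' On a violation the chain is closed and a new one starts at the violating
#' anchor. Chains with at least `min_genes` anchors and anchor density at
#' least `min_density` (anchors / genes spanned on A) are emitted. If a
#' gene appears in several anchor pairs, only its best-scoring pair is used
#' (tandem-duplicate de-inflation); each anchor thus joins at most one
#' block.
#'
#' @param order_a,order_b gene orders (see [gene_order()]).
#' @param anchors data.frame `gene_a`, `gene_b`, optional `score`.
#' @param params [synteny_params()].
#' @return data.frame, one row per block: scaffold pair, anchor count,
#'   spans on both genomes, `orientation` (`same`/`inverted`), `density`,
#'   and the anchor gene lists (list columns `genes_a`, `genes_b`).
#' @export
build_blocks <- function(order_a, order_b, anchors,
                         params = synteny_params()) {
  empty <- data.frame(scaf_a = character(0), scaf_b = character(0),
                      n_anchors = integer(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), orientation = character(0),
                      density = numeric(0))
  if (nrow(anchors) == 0L) { empty$genes_a <- list(); empty$genes_b <- list(); return(empty) }
  if (!is.null(anchors$score)) {
    ord <- order(-anchors$score)
    anchors <- anchors[ord, , drop = FALSE]
    anchors <- anchors[!duplicated(anchors$gene_a) &
                         !duplicated(anchors$gene_b), , drop = FALSE]
  }
  ap <- anchor_positions(order_a, order_b, anchors)
  ap <- ap[order(ap$scaf_a, ap$pos_a), , drop = FALSE]
  # anchor rank on genome B within each B scaffold: chain extension must
  # step to the adjacent anchor in rank (skipping an anchored gene on B is
  # a break; max_gap tolerates unanchored genes only)
  ap$rank_b <- NA_integer_
  for (sb in unique(ap$scaf_b)) {
    idx <- which(ap$scaf_b == sb)
    ap$rank_b[idx] <- rank(ap$pos_b[idx])
  }
  blocks <- list()
  flush <- function(idx) {
    if (length(idx) < params$min_genes) return(invisible(NULL))
    pos_a <- ap$pos_a[idx]; pos_b <- ap$pos_b[idx]
    span_a <- max(pos_a) - min(pos_a) + 1L
    dens <- length(idx) / span_a
    if (dens < params$min_density) return(invisible(NULL))
    orientation <- if (pos_b[2] > pos_b[1]) "same" else "inverted"
    blocks[[length(blocks) + 1L]] <<- data.frame(
      scaf_a = ap$scaf_a[idx[1]], scaf_b = ap$scaf_b[idx[1]],
      n_anchors = length(idx),
      start_a = min(pos_a), end_a = max(pos_a),
      start_b = min(pos_b), end_b = max(pos_b),
      orientation = orientation, density = dens,
      genes_a = I(list(ap$gene_a[idx])), genes_b = I(list(ap$gene_b[idx])),
      stringsAsFactors = FALSE)
  }
  cur <- integer(0)
  dir <- 0L
  for (r in seq_len(nrow(ap))) {
    ok <- FALSE
    if (length(cur)) {
      p <- cur[length(cur)]
      gap_a <- ap$pos_a[r] - ap$pos_a[p] - 1L
      step_b <- ap$pos_b[r] - ap$pos_b[p]
      gap_b <- abs(step_b) - 1L
      step_rank <- ap$rank_b[r] - ap$rank_b[p]
      same_scafs <- ap$scaf_a[r] == ap$scaf_a[p] &&
        ap$scaf_b[r] == ap$scaf_b[p]
      if (same_scafs && gap_a <= params$max_gap && gap_b <= params$max_gap &&
          abs(step_rank) == 1L) {
        if (dir == 0L) { ok <- TRUE; dir <- sign(step_b) }
        else ok <- (sign(step_b) == dir)
      }
    }
    if (ok) cur <- c(cur, r)
    else { flush(cur); cur <- r; dir <- 0L }
  }
  flush(cur)
  if (!length(blocks)) { empty$genes_a <- list(); empty$genes_b <- list(); return(empty) }
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res
}

#' Classify genes as syntenic or non-syntenic
#'
#' Anchor genes and genes lying inside a block span are syntenic. Outside
#' block spans, a maximal run of at least `break_run` consecutive
#' uncovered genes is a break in synteny and its genes are non-syntenic;
#' shorter interruptions are tolerated and count as syntenic.
#'
#' @param order gene order of the classified genome.
#' @param blocks blocks built with this genome as the reference (side `a`)
#'   or target (side `b`) axis.
#' @param side which side of `blocks` this genome is (`"a"` or `"b"`).
#' @param break_run break threshold (default 3).
#' @return data.frame `gene_id`, `scaffold_id`, `position`, `class`.
#' @export
classify_genes <- function(order, blocks, side = c("a", "b"),
                           break_run = 3) {
  side <- match.arg(side)
  scaf_col <- paste0("scaf_", side)
  lo_col <- paste0("start_", side); hi_col <- paste0("end_", side)
  covered <- rep(FALSE, nrow(order))
  if (nrow(blocks) > 0L) for (b in seq_len(nrow(blocks))) {
    covered <- covered |
      (order$scaffold_id == blocks[[scaf_col]][b] &
         order$position >= blocks[[lo_col]][b] &
         order$position <= blocks[[hi_col]][b])
  }
  cls <- rep("syntenic", nrow(order))
  for (sc in unique(order$scaffold_id)) {
    idx <- which(order$scaffold_id == sc)
    r <- rle(!covered[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= break_run)
        cls[idx[starts[k]:ends[k]]] <- "non_syntenic"
    }
  }
  data.frame(gene_id = order$gene_id, scaffold_id = order$scaffold_id,
             position = order$position, class = cls,
             stringsAsFactors = FALSE)
}

#' Permutation null for synteny block statistics
#'
#' Shuffles genome B's gene order uniformly (genes reassigned to the
#' existing scaffold/position slots), rebuilds blocks, and reports the null
#' distribution of block count and maximum block size together with the
#' empirical p-value for the observed maximum block size,
#' `(1 + #{null >= observed}) / (n_shuffles + 1)`.
#'
#' @param order_a,order_b gene orders.
#' @param anchors anchor table as for [build_blocks()].
#' @param params [synteny_params()].
#' @param n_shuffles number of permutations (>= 1).
#' @param seed RNG seed.
#' @return List: `observed` (n_blocks, max_size), `null` (data.frame),
#'   `p_max_size`.
#' @export
shuffle_null <- function(order_a, order_b, anchors,
                         params = synteny_params(), n_shuffles = 100,
                         seed = 1) {
  stopifnot(n_shuffles >= 1)
  obs <- build_blocks(order_a, order_b, anchors, params)
  obs_stat <- c(n_blocks = nrow(obs),
                max_size = if (nrow(obs)) max(obs$n_anchors) else 0L)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(s) {
    ob <- order_b
    ob$gene_id <- sample(ob$gene_id)
    nb <- build_blocks(order_a, ob, anchors, params)
    c(if (nrow(nb)) nrow(nb) else 0L,
      if (nrow(nb)) max(nb$n_anchors) else 0L)
  }, numeric(2))
  null <- data.frame(n_blocks = null[1, ], max_size = null[2, ])
  p <- (1 + sum(null$max_size >= obs_stat["max_size"])) / (n_shuffles + 1)
  list(observed = obs_stat, null = null, p_max_size = unname(p))
}

#' Block-size spectrum
#'
#' Histogram of block sizes (anchors per block) plus the Spearman
#' correlation between size and count; under random breakage small blocks
#' outnumber large ones, giving a negative correlation.
#'
#' @param blocks output of [build_blocks()].
#' @return List: `histogram` (data.frame `size`, `count`), `spearman_rho`.
#' @export
block_size_spectrum <- function(blocks) {
  if (nrow(blocks) == 0L)
    return(list(histogram = data.frame(size = integer(0), count = integer(0)),
                spearman_rho = NA_real_))
  tab <- table(blocks$n_anchors)
  hist <- data.frame(size = as.integer(names(tab)),
                     count = as.integer(tab))
  rho <- if (nrow(hist) > 2)
    suppressWarnings(cor(hist$size, hist$count, method = "spearman"))
  else NA_real_
  list(histogram = hist, spearman_rho = rho)
}

#' 2x2 enrichment test
#'
#' Fisher's exact test (two-sided and one-sided) plus Pearson chi-square
#' with continuity correction on the table `rbind(c(a, b), c(c, d))`. The
#' odds ratio is the sample (a d)/(b c) with a Haldane 0.5 correction when
#' any cell is zero. A log10 one-sided hypergeometric tail is reported so
#' extreme significance is not floored at the double-precision limit.
#'
#' @param a,b,c,d non-negative integer cell counts (row 1: a, b; row 2: c,
#'   d).
#' @return List of class `contingency_result`: `table`, `odds_ratio`,
#'   `p_two_sided`, `p_one_sided` (alternative: odds ratio > 1),
#'   `log10_p_one_sided`, `p_chisq`, `test`.
#' @export
enrichment_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero margin")
  ft2 <- fisher.test(m, alternative = "two.sided")
  ft1 <- fisher.test(m, alternative = "greater")
  chi <- suppressWarnings(chisq.test(m, correct = TRUE))
  or <- if (any(m == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
        else (a * d) / (b * c)
  # P(X >= a) for X ~ Hypergeom(row1 total draws from col1/col2 urn)
  log10p1 <- phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE,
                    log.p = TRUE) / log(10)
  structure(list(table = m, odds_ratio = or,
                 p_two_sided = ft2$p.value, p_one_sided = ft1$p.value,
                 log10_p_one_sided = log10p1, p_chisq = chi$p.value,
                 test = "fisher_exact"), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "<2x2 enrichment> OR = %.3f, two-sided p = %.3g, one-sided p = %.3g (log10 = %.1f)\n",
    x$odds_ratio, x$p_two_sided, x$p_one_sided, x$log10_p_one_sided))
  invisible(x)
}

#' Per-category enrichment in non-syntenic regions
#'
#' One Fisher 2x2 per category label (in-category vs not, crossed with
#' non-syntenic vs syntenic), with Benjamini-Hochberg adjusted q-values.
#'
#' @param classification output of [classify_genes()] (or a concatenation
#'   across species).
#' @param categories data.frame `gene_id`, `category` (genes absent from
#'   the table count as unlabelled).
#' @return data.frame sorted by q-value: per-category counts, odds ratio,
#'   `p_value`, `q_value`.
#' @export
category_enrichment <- function(classification, categories) {
  cls <- classification
  cls$category <- categories$category[match(cls$gene_id, categories$gene_id)]
  ns <- cls$class == "non_syntenic"
  cats <- sort(unique(cls$category[!is.na(cls$category)]))
  if (!length(cats))
    return(data.frame(category = character(0)))
  rows <- lapply(cats, function(cc) {
    inc <- !is.na(cls$category) & cls$category == cc
    a <- sum(inc & ns); b <- sum(inc & !ns)
    c_ <- sum(!inc & ns); d <- sum(!inc & !ns)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or <- if (b * c_ == 0) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
          else (a * d) / (b * c_)
    data.frame(category = cc, n_category = a + b,
               n_nonsyntenic_in_category = a, odds_ratio = or,
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$q_value, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
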