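# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive each quantity from first principles (plain
# loops, exhaustive enumeration) and never call the package functions they
# check.

# -- quadratic-space affine-gap Smith-Waterman score (Gotoh) -------------
sw_score_oracle <- function(a, b, open = 11, ext = 1, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    M[i, j] <- max(0,
                   max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                     mat[av[i - 1], bv[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

# -- NG86 via fresh pathway enumeration ----------------------------------
ng86_oracle <- function(codons_a, codons_b) {
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    cv <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (bb in setdiff(bases, cv[p])) {
      alt <- cv; alt[p] <- bb
      if (gc_tab[[paste(alt, collapse = "")]] == gc_tab[[cod]]) s <- s + 1
    }
    s / 3
  }
  count_path <- function(from, to, positions) {
    # recursive enumeration of orderings; returns matrix of (sd, nd, valid)
    if (!length(positions)) return(matrix(c(0, 0, 1), 1))
    out <- NULL
    for (p in positions) {
      nxt <- from; nxt[p] <- to[p]
      nc <- paste(nxt, collapse = "")
      step_valid <- !(gc_tab[[nc]] == "*" && !identical(nxt, to))
      step_syn <- gc_tab[[paste(from, collapse = "")]] == gc_tab[[nc]]
      rest <- count_path(nxt, to, setdiff(positions, p))
      rest[, 1] <- rest[, 1] + as.numeric(step_syn)
      rest[, 2] <- rest[, 2] + as.numeric(!step_syn)
      rest[, 3] <- rest[, 3] * as.numeric(step_valid)
      out <- rbind(out, rest)
    }
    out
  }
  S <- 0; sd <- 0; nd <- 0
  for (k in seq_along(codons_a)) {
    S <- S + (syn_sites(codons_a[k]) + syn_sites(codons_b[k])) / 2
    ca <- strsplit(codons_a[k], "")[[1]]; cb <- strsplit(codons_b[k], "")[[1]]
    dp <- which(ca != cb)
    if (!length(dp)) next
    paths <- count_path(ca, cb, dp)
    use <- paths[, 3] == 1
    if (!any(use)) use <- rep(TRUE, nrow(paths))
    sd <- sd + mean(paths[use, 1])
    nd <- nd + mean(paths[use, 2])
  }
  N <- 3 * length(codons_a) - S
  ps <- sd / S; pn <- nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

# -- two-sided Fisher p by exhaustive hypergeometric enumeration ---------
fisher2x2_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# -- two-sided exact Wilcoxon rank-sum p by enumeration ------------------
wilcox_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_r <- rank(c(x, y))  # no ties assumed
  ws <- apply(combos, 2, function(idx) sum(all_r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# -- dense reference Markov clustering -----------------------------------
mcl_oracle <- function(edges, nodes, inflation = 2, tol = 1e-6,
                       max_iter = 100) {
  nodes <- sort(nodes)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- edges$weight[r]
    A[edges$to[r], edges$from[r]] <- edges$weight[r]
  }
  for (i in seq_len(n)) {
    mx <- max(A[i, ])
    A[i, i] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
  for (it in seq_len(max_iter)) {
    B <- A %*% A
    B <- B^inflation
    for (j in seq_len(n)) B[, j] <- B[, j] / sum(B[, j])
    if (max(abs(B - A)) < tol) { A <- B; break }
    A <- B
  }
  cl <- rep(NA_integer_, n)
  fam <- 0L
  for (i in seq_len(n)) {
    if (A[i, i] <= tol) next
    memb <- which(A[i, ] > tol)
    memb <- memb[is.na(cl[memb])]
    if (!length(memb)) next
    if (!is.na(cl[i])) { cl[memb] <- cl[i]; next }
    fam <- fam + 1L
    cl[c(i, memb)] <- fam
  }
  for (i in which(is.na(cl))) { fam <- fam + 1L; cl[i] <- fam }
  split(nodes, cl)
}

# -- greedy chain construction, independent transcription ----------------
chain_oracle <- function(order_a, order_b, anchors, params) {
  pa <- setNames(order_a$position, order_a$gene_id)
  sa <- setNames(order_a$scaffold_id, order_a$gene_id)
  pb <- setNames(order_b$position, order_b$gene_id)
  sb <- setNames(order_b$scaffold_id, order_b$gene_id)
  df <- data.frame(ga = anchors$gene_a, gb = anchors$gene_b,
                   sa = sa[anchors$gene_a], pa = pa[anchors$gene_a],
                   sb = sb[anchors$gene_b], pb = pb[anchors$gene_b],
                   stringsAsFactors = FALSE)
  df <- df[order(df$sa, df$pa), ]
  df$rb <- NA_real_
  for (s in unique(df$sb)) df$rb[df$sb == s] <- rank(df$pb[df$sb == s])
  chains <- list(); cur <- integer(0); dir <- 0
  close_chain <- function() {
    if (length(cur) >= params$min_genes) {
      span <- max(df$pa[cur]) - min(df$pa[cur]) + 1
      if (length(cur) / span >= params$min_density)
        chains[[length(chains) + 1]] <<- cur
    }
  }
  for (r in seq_len(nrow(df))) {
    extend <- FALSE
    if (length(cur)) {
      p <- cur[length(cur)]
      if (df$sa[r] == df$sa[p] && df$sb[r] == df$sb[p] &&
          (df$pa[r] - df$pa[p] - 1) <= params$max_gap &&
          (abs(df$pb[r] - df$pb[p]) - 1) <= params$max_gap &&
          abs(df$rb[r] - df$rb[p]) == 1) {
        if (dir == 0) { extend <- TRUE; dir <- sign(df$pb[r] - df$pb[p]) }
        else extend <- sign(df$pb[r] - df$pb[p]) == dir
      }
    }
    if (extend) cur <- c(cur, r)
    else { close_chain(); cur <- r; dir <- 0 }
  }
  close_chain()
  lapply(chains, function(idx)
    list(genes_a = df$ga[idx],
         orientation = if (df$pb[idx[2]] > df$pb[idx[1]]) "same" else "inverted"))
}

# canonical comparable form of build_blocks output
blocks_canonical <- function(blocks) {
  if (nrow(blocks) == 0L) return(list())
  out <- lapply(seq_len(nrow(blocks)), function(i)
    list(genes_a = blocks$genes_a[[i]], orientation = blocks$orientation[i]))
  out[order(vapply(out, function(x) x$genes_a[1], ""))]
}
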