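# Shared codon bookkeeping for the substitution simulator and the
# Nei-Gojobori estimator. Tables are built once per session and memoized.

.triclade_env <- new.env(parent = emptyenv())

#' @noRd
codon_tables <- function() {
  if (!is.null(.triclade_env$ct)) return(.triclade_env$ct)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  sense <- codons[gc_tab != "*"]
  bases <- c("A", "C", "G", "T")
  # single-base variants of each sense codon, split by effect
  syn_var <- vector("list", length(sense))
  nonsyn_var <- vector("list", length(sense))  # excludes stop-producing
  syn_n <- integer(length(sense))              # of the 9 possible changes
  names(syn_var) <- names(nonsyn_var) <- names(syn_n) <- sense
  for (cd in sense) {
    aa <- gc_tab[[cd]]
    sv <- character(0); nv <- character(0); ns <- 0L
    cv <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in bases) {
      if (b == cv[pos]) next
      alt <- cv; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      alt_aa <- gc_tab[[altc]]
      if (alt_aa == aa) { sv <- c(sv, altc); ns <- ns + 1L }
      else if (alt_aa != "*") nv <- c(nv, altc)
    }
    syn_var[[cd]] <- sv; nonsyn_var[[cd]] <- nv; syn_n[[cd]] <- ns
  }
  # NG86 synonymous site count per codon: (# synonymous changes)/3;
  # stop-producing changes count toward the nonsynonymous side.
  s_sites <- syn_n / 3
  .triclade_env$ct <- list(gc = gc_tab, sense = sense, syn_var = syn_var,
                           nonsyn_var = nonsyn_var, syn_n = syn_n,
                           s_sites = s_sites)
  .triclade_env$ct
}

# Average synonymous/nonsynonymous difference counts between every pair of
# sense codons, averaging over all shortest mutational pathways with equal
# weight; pathways passing through a stop codon are excluded (if every
# pathway is excluded, all pathways are used as a fallback).
#' @noRd
ng86_pair_tables <- function() {
  if (!is.null(.triclade_env$ngtab)) return(.triclade_env$ngtab)
  ct <- codon_tables()
  sense <- ct$sense
  gc_tab <- ct$gc
  n <- length(sense)
  SD <- matrix(0, n, n, dimnames = list(sense, sense))
  ND <- matrix(0, n, n, dimnames = list(sense, sense))
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n)) {
    ci <- strsplit(sense[i], "")[[1]]
    for (j in seq_len(n)) {
      if (j <= i) next
      cj <- strsplit(sense[j], "")[[1]]
      diffpos <- which(ci != cj)
      k <- length(diffpos)
      if (k == 0L) next
      pm <- perms[[as.character(k)]]
      path_sd <- numeric(0); path_nd <- numeric(0); path_ok <- logical(0)
      for (p in seq_len(nrow(pm))) {
        cur <- ci; sd <- 0; nd <- 0; ok <- TRUE
        for (step in pm[p, seq_len(k)]) {
          nxt <- cur; nxt[diffpos[step]] <- cj[diffpos[step]]
          a1 <- gc_tab[[paste(cur, collapse = "")]]
          a2 <- gc_tab[[paste(nxt, collapse = "")]]
          if (a2 == "*" && !identical(nxt, cj)) ok <- FALSE
          if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
        path_ok <- c(path_ok, ok)
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
      SD[i, j] <- SD[j, i] <- mean(path_sd[use])
      ND[i, j] <- ND[j, i] <- mean(path_nd[use])
    }
  }
  .triclade_env$ngtab <- list(SD = SD, ND = ND)
  .triclade_env$ngtab
}

#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}
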