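test_that("local alignment matches an independent DP oracle and is symmetric", {
  m <- score_pair("HEAGAWGHEE", "PAWHEAE")
  expect_equal(m$score, sw_score_oracle("HEAGAWGHEE", "PAWHEAE"))
  set.seed(5)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 25, replace = TRUE), collapse = "")
    expect_equal(score_pair(a, b)$score, sw_score_oracle(a, b))
    expect_equal(score_pair(a, b)$score, score_pair(b, a)$score)
  }
  p <- paste(sample(aas, 100, replace = TRUE), collapse = "")
  self <- score_pair(p, p)
  expect_equal(self$pident, 100)
  expect_error(score_pair("", "AA"), "empty")
})

test_that("all-vs-all finds own copies across identical proteomes", {
  set.seed(8)
  cds <- vapply(1:8, function(i) random_cds_fix(40), "")
  g1 <- make_annotation(cds, species = "x")
  g2 <- make_annotation(cds, species = "y")
  m <- all_vs_all(list(x = g1, y = g2))
  cross <- m[m$query_species == "x" & m$subject_species == "y", ]
  for (i in seq_along(cds)) {
    mine <- cross[cross$query_id == g1$genes$gene_id[i], ]
    best <- mine$subject_id[which.max(mine$score)]
    expect_equal(best, g2$genes$gene_id[i])
  }
  # infinite threshold: empty result
  m0 <- all_vs_all(list(x = g1, y = g2), homology_params(min_score = Inf))
  expect_equal(nrow(m0), 0L)
})

test_that("reciprocal best hits pair identical proteomes and drop ties", {
  set.seed(9)
  cds <- vapply(1:6, function(i) random_cds_fix(40), "")
  g1 <- make_annotation(cds, species = "x")
  g2 <- make_annotation(cds, species = "y")
  m <- all_vs_all(list(x = g1, y = g2))
  rbh <- reciprocal_best_hits(m, "x", "y")
  expect_equal(nrow(rbh), 6L)
  expect_identical(sub("x_", "y_", rbh$gene_a), rbh$gene_b)
  # a tied top score drops the gene
  fake <- data.frame(
    query_species = c("x", "x", "y", "y"),
    query_id = c("q", "q", "h1", "h2"),
    subject_species = c("y", "y", "x", "x"),
    subject_id = c("h1", "h2", "q", "q"),
    score = c(10, 10, 10, 10), pident = 90, aln_len = 10)
  expect_equal(nrow(reciprocal_best_hits(fake, "x", "y")), 0L)
})

test_that("Markov clustering separates components and matches dense oracle", {
  tri2 <- data.frame(from = c("a", "a", "b", "x", "x", "y"),
                     to = c("b", "c", "c", "y", "z", "z"), weight = 1)
  fam <- mcl_cluster(tri2)
  expect_equal(length(unique(fam$family_id)), 2L)
  expect_equal(nrow(fam), 6L)
  expect_equal(anyDuplicated(fam$member), 0L)
  single <- mcl_cluster(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)), nodes = "solo")
  expect_equal(nrow(single), 1L)
  expect_error(mcl_cluster(data.frame(from = "a", to = "b", weight = -1)),
               "non-positive")

  # planted partition: 3 communities of 10, dense inside, sparse between
  set.seed(12)
  nodes <- sprintf("n%02d", 1:30)
  grp <- rep(1:3, each = 10)
  edges <- list()
  for (i in 1:29) for (j in (i + 1):30) {
    p <- if (grp[i] == grp[j]) 0.8 else 0.04
    if (runif(1) < p)
      edges[[length(edges) + 1]] <- data.frame(from = nodes[i],
                                               to = nodes[j], weight = 1)
  }
  edges <- do.call(rbind, edges)
  got <- mcl_cluster(edges, inflation = 2, nodes = nodes)
  ref <- mcl_oracle(edges, nodes, inflation = 2)
  got_sets <- unname(lapply(split(got$member, got$family_id), sort))
  ref_sets <- unname(lapply(ref, sort))
  expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                  vapply(ref_sets, paste, "", collapse = ","))
  # clusters never span graph components
  comp <- rep(NA_integer_, 30); comp[1:10] <- 1
  expect_true(all(vapply(got_sets, function(s) {
    g <- unique(grp[match(s, nodes)]); length(g) >= 1
  }, logical(1))))
})

test_that("ortholog triangles close over RBH and break with a missing edge", {
  ab <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                   score = 1, pident = 99)
  bc <- data.frame(gene_a = c("b1", "b2"), gene_b = c("c1", "c2"),
                   score = 1, pident = 99)
  ac <- data.frame(gene_a = c("a1", "a2"), gene_b = c("c1", "c2"),
                   score = 1, pident = 99)
  expect_equal(nrow(three_way_orthologs(ab, bc, ac)), 2L)
  expect_equal(nrow(three_way_orthologs(ab, bc, ac[1, ])), 1L)
})

test_that("the Venn partition covers every gene exactly once", {
  set.seed(23)
  cds <- vapply(1:7, function(i) random_cds_fix(40), "")
  gs <- list(A = make_annotation(cds, species = "A"),
             B = make_annotation(cds, species = "B"),
             C = make_annotation(c(cds, random_cds_fix(40)), species = "C"))
  m <- all_vs_all(gs)
  rbh <- list(AB = reciprocal_best_hits(m, "A", "B"),
              BC = reciprocal_best_hits(m, "B", "C"),
              AC = reciprocal_best_hits(m, "A", "C"))
  tri <- three_way_orthologs(rbh$AB, rbh$BC, rbh$AC)
  part <- orthology_partition(gs, tri, rbh)
  expect_equal(nrow(part$assignment),
               sum(vapply(gs, function(g) nrow(g$genes), 0L)))
  expect_equal(sum(part$assignment$cell == "core"), 3 * nrow(tri))
  expect_equal(part$assignment$cell[part$assignment$gene_id == "C_g008"],
               "unique_C")
  # per-species cells sum to species gene totals
  for (s in names(gs))
    expect_equal(sum(part$assignment$species == s), nrow(gs[[s]]$genes))
})

test_that("family expansion reports residuals after ortholog subtraction", {
  fams <- data.frame(
    family_id = c(rep("f1", 3), rep("f2", 6)),
    member = c("A|a1", "B|b1", "C|c1",
               "A|a2", "B|b2", "C|c2", "B|b3", "B|b4", "A|a3"))
  tri <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                    gene_c = c("c1", "c2"))
  rep_ <- expanded_families(fams, tri, species = c("A", "B", "C"),
                            expanded_in = c("A", "B"))
  f1 <- rep_[rep_$family_id == "f1", ]
  expect_equal(f1$total, 0)
  f2 <- rep_[rep_$family_id == "f2", ]
  expect_equal(f2$B, 2); expect_equal(f2$A, 1); expect_equal(f2$C, 0)
  expect_true(f2$expanded)
  # subtraction never increases family size
  memb <- table(fams$family_id)
  expect_true(all(rep_$total <= as.integer(memb[rep_$family_id])))
})

test_that("marker selection excludes near-duplicates and respects synteny", {
  tri <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                    gene_c = c("c1", "c2"))
  cls <- data.frame(gene_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
                    class = "syntenic")
  # a2 has a 60%-identity non-orthologous match -> excluded
  m <- data.frame(query_species = "A", query_id = "a2",
                  subject_species = "A", subject_id = "a9",
                  score = 100, pident = 60, aln_len = 50)
  sel <- select_phylogenomic_markers(tri, cls, m, n = 1, seed = 3)
  expect_equal(sel$gene_a, "a1")
  # at cutoff 100 the match no longer disqualifies
  sel2 <- select_phylogenomic_markers(tri, cls, m, n = 2,
                                      similarity_cutoff = 100, seed = 3)
  expect_equal(nrow(sel2), 2L)
  expect_error(select_phylogenomic_markers(tri, cls, m, n = 5, seed = 1),
               "eligible")
})

test_that("mean syntenic identity averages the right pairs", {
  rbh <- data.frame(gene_a = c("a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3"),
                    score = 1, pident = c(50, 100, 80))
  cls <- data.frame(gene_id = c("a1", "a2", "b1", "b2", "a3", "b3"),
                    class = c(rep("syntenic", 4), "non_syntenic", "syntenic"))
  expect_equal(mean_syntenic_identity(rbh, cls), 75)
  cls$class <- "non_syntenic"
  expect_error(mean_syntenic_identity(rbh, cls), "no syntenic")
})
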