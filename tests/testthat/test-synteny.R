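test_that("identical orders chain into one full-length block", {
  a <- make_order(paste0("a", 1:10)); b <- make_order(paste0("b", 1:10))
  anch <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10))
  bl <- build_blocks(a, b, anch)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$n_anchors, 10L)
  expect_equal(bl$orientation, "same")
  expect_equal(nrow(build_blocks(a, b, anch[0, ])), 0L)
  expect_error(build_blocks(a, b, data.frame(gene_a = "zz", gene_b = "b1")),
               "absent")
})

test_that("an internal inversion splits the chain into three oriented blocks", {
  a <- make_order(paste0("a", 1:10))
  b <- make_order(paste0("b", 1:10))
  anch <- data.frame(gene_a = paste0("a", 1:10),
                     gene_b = paste0("b", c(1:3, 6, 5, 4, 7:10)))
  bl <- build_blocks(a, b, anch)
  expect_equal(nrow(bl), 3L)
  expect_equal(bl$orientation, c("same", "inverted", "same"))
  expect_equal(bl$n_anchors, c(3L, 3L, 4L))
  # anchors of the inverted block have strictly decreasing B positions
  inv_genes <- bl$genes_b[[2]]
  pos <- match(inv_genes, b$gene_id)
  expect_true(all(diff(pos) < 0))
})

test_that("greedy chaining equals the independent enumerator on random instances", {
  set.seed(99)
  params <- synteny_params()
  for (i in 1:250) {
    n <- sample(4:15, 1)
    a <- make_order(paste0("a", 1:n))
    perm <- sample(n)
    keep <- sort(sample(n, sample(3:n, 1)))
    anch <- data.frame(gene_a = paste0("a", keep),
                       gene_b = paste0("b", perm[keep]))
    b <- make_order(paste0("b", 1:n))
    got <- blocks_canonical(build_blocks(a, b, anch, params))
    ref <- chain_oracle(a, b, anch, params)
    ref <- ref[order(vapply(ref, function(x) x$genes_a[1], ""))]
    expect_equal(length(got), length(ref))
    for (k in seq_along(got)) {
      expect_identical(got[[k]]$genes_a, ref[[k]]$genes_a)
      expect_identical(got[[k]]$orientation, ref[[k]]$orientation)
    }
  }
})

test_that("classification applies the three-gene break rule", {
  b <- make_order(paste0("b", 1:10))
  anch <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10))
  # fully anchored: everything syntenic
  a0 <- make_order(paste0("a", 1:10))
  cl0 <- classify_genes(a0, build_blocks(a0, b, anch))
  expect_true(all(cl0$class == "syntenic"))
  # three novel genes between blocks: non-syntenic
  a3 <- make_order(c(paste0("a", 1:5), paste0("n", 1:3), paste0("a", 6:10)))
  cl3 <- classify_genes(a3, build_blocks(a3, b, anch))
  expect_equal(cl3$class[cl3$gene_id %in% paste0("n", 1:3)],
               rep("non_syntenic", 3))
  expect_true(all(cl3$class[grepl("^a", cl3$gene_id)] == "syntenic"))
  # two novel genes: tolerated as syntenic
  a2 <- make_order(c(paste0("a", 1:5), paste0("n", 1:2), paste0("a", 6:10)))
  cl2 <- classify_genes(a2, build_blocks(a2, b, anch))
  expect_true(all(cl2$class == "syntenic"))
  # the partition is total
  expect_setequal(unique(c(cl0$class, cl2$class, cl3$class)),
                  c("syntenic", "non_syntenic"))
})

test_that("the permutation null behaves on conserved orders", {
  a <- make_order(paste0("a", 1:12)); b <- make_order(paste0("b", 1:12))
  anch <- data.frame(gene_a = paste0("a", 1:12), gene_b = paste0("b", 1:12))
  sn <- shuffle_null(a, b, anch, n_shuffles = 100, seed = 4)
  expect_equal(sn$observed[["max_size"]], 12)
  expect_true(all(sn$null$max_size <= 12))
  expect_equal(sn$p_max_size, 1 / 101, tolerance = 1e-9)
  sn2 <- shuffle_null(a, b, anch, n_shuffles = 100, seed = 4)
  expect_identical(sn$null, sn2$null)
  sn0 <- shuffle_null(a, b, anch[0, ], n_shuffles = 5, seed = 1)
  expect_equal(unname(sn0$observed["n_blocks"]), 0)
})

test_that("the block-size spectrum conserves counts", {
  a <- make_order(paste0("a", 1:20))
  b <- make_order(paste0("b", c(1:5, 8, 7, 6, 9:12, 15, 14, 13, 16:20)))
  anch <- data.frame(gene_a = paste0("a", 1:20), gene_b = paste0("b", 1:20))
  bl <- build_blocks(a, b, anch)
  sp <- block_size_spectrum(bl)
  expect_equal(sum(sp$histogram$count), nrow(bl))
  one <- block_size_spectrum(bl[1, ])
  expect_equal(nrow(one$histogram), 1L)
})

test_that("2x2 enrichment matches hypergeometric enumeration", {
  flat <- enrichment_2x2(5, 5, 5, 5)
  expect_equal(flat$p_two_sided, 1.0)
  ex <- enrichment_2x2(2, 1, 1, 2)
  expect_equal(ex$p_two_sided, fisher2x2_oracle(2, 1, 1, 2))
  set.seed(77)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    e <- enrichment_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(e$p_two_sided,
                 fisher2x2_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  # Haldane-corrected odds ratio for zero cells
  z <- enrichment_2x2(0, 5, 5, 5)
  expect_equal(z$odds_ratio, (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(enrichment_2x2(0, 0, 3, 4), "margin")
})

test_that("category enrichment is calibrated and BH-monotone", {
  set.seed(15)
  n <- 600
  cls <- data.frame(gene_id = sprintf("g%04d", 1:n), scaffold_id = "s1",
                    position = 1:n,
                    class = sample(c("syntenic", "non_syntenic"), n,
                                   replace = TRUE, prob = c(.85, .15)))
  cats <- data.frame(gene_id = cls$gene_id,
                     category = sample(paste0("PF", 1:6), n, replace = TRUE))
  res <- category_enrichment(cls, cats)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # q monotone in p
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  expect_true(min(res$q_value) > 0.05)  # uniform category: no signal
})
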