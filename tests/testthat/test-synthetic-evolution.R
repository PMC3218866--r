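test_that("simulation is deterministic under a fixed seed", {
  cfg <- clade_config(seed = 5, n_genes = 15, n_te_families = 1,
                      te_copies_per_family = 3)
  expect_identical(simulate_ancestor(cfg), simulate_ancestor(cfg))
  s1 <- simulate_clade(cfg)
  s2 <- simulate_clade(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth$ortholog_map, s2$truth$ortholog_map)
})

test_that("ancestor genes carry start codons and no internal stops", {
  cfg <- clade_config(seed = 2, n_genes = 25)
  anc <- simulate_ancestor(cfg)
  expect_true(all(substr(anc$genes$cds, 1, 3) == "ATG"))
  expect_false(any(grepl("\\*", anc$genes$protein)))
  # degenerate case: empty genome accepted
  empty <- simulate_ancestor(clade_config(seed = 1, n_genes = 0,
                                          n_te_families = 0))
  expect_equal(nrow(empty$genes), 0L)
})

test_that("an all-zero branch is the identity", {
  set.seed(3)
  ann <- make_annotation(vapply(1:6, function(i) random_cds_fix(15), ""))
  res <- evolve_branch(ann, branch_params(ka = 0, ks = 0, n_inversions = 0,
                                          n_duplications = 0, n_losses = 0,
                                          te_insertions = 0))
  expect_equal(res$genome$genes, ann$genes)
  expect_equal(res$genome$scaffolds, ann$scaffolds)
})

test_that("a zero-event clade yields three identical all-ortholog genomes", {
  s <- simulate_clade(quiet_config(seed = 9, n_genes = 12))
  expect_identical(s$genomes$A$genes$cds, s$genomes$B$genes$cds)
  expect_identical(s$genomes$B$genes$cds, s$genomes$C$genes$cds)
  expect_true(all(stats::complete.cases(s$truth$ortholog_map)))
})

test_that("inversions flip strands of a contiguous window and preserve gene sets", {
  set.seed(7)
  ann <- make_annotation(vapply(1:10, function(i) random_cds_fix(12), ""))
  res <- evolve_branch(ann, branch_params(ka = 0, ks = 0, n_inversions = 1,
                                          inversion_len_genes = c(3, 3),
                                          n_duplications = 0, n_losses = 0,
                                          te_insertions = 0))
  out <- res$genome$genes
  expect_setequal(out$gene_id, ann$genes$gene_id)
  inv <- res$truth$inversions[[1]]
  expect_equal(length(inv$gene_ids), 3L)
  flipped <- out$gene_id %in% inv$gene_ids
  expect_true(all(out$strand[flipped] == "-"))
  expect_true(all(out$strand[!flipped] == "+"))
  # the inverted trio appears in reversed order
  orig_pos <- match(inv$gene_ids, ann$genes$gene_id)
  new_pos <- match(inv$gene_ids, out$gene_id)
  expect_equal(order(new_pos), rev(order(orig_pos)))
})

test_that("gene counts obey before - losses + duplications", {
  set.seed(13)
  ann <- make_annotation(vapply(1:20, function(i) random_cds_fix(12), ""))
  res <- evolve_branch(ann, branch_params(n_duplications = 5, n_losses = 3,
                                          te_insertions = 0))
  expect_equal(nrow(res$genome$genes),
               20 - length(res$truth$losses) + nrow(res$truth$duplications))
  expect_error(evolve_branch(ann, branch_params(n_losses = 50)),
               "losses exceed")
})

test_that("RIP performs only CpA/TpG transitions and preserves length", {
  set.seed(21)
  r <- apply_rip("CACA", 1, 1.0)
  expect_equal(r$seq, "TATA"); expect_equal(r$n_mutations, 2L)
  r <- apply_rip("TGTG", 1, 1.0)
  expect_equal(r$seq, "TATA"); expect_equal(r$n_mutations, 2L)
  r <- apply_rip("GGCC", 3, 1.0)
  expect_equal(r$seq, "GGCC"); expect_equal(r$n_mutations, 0L)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    r <- apply_rip(s, 2, 0.3)
    expect_equal(nchar(r$seq), nchar(s))
    a <- strsplit(s, "")[[1]]; b <- strsplit(r$seq, "")[[1]]
    ch <- which(a != b)
    expect_true(all((a[ch] == "C" & b[ch] == "T") |
                      (a[ch] == "G" & b[ch] == "A")))
  }
})

test_that("truth ortholog count equals genes minus lineage losses", {
  cfg <- clade_config(seed = 17, n_genes = 40)
  s <- simulate_clade(cfg)
  om <- s$truth$ortholog_map
  bt <- s$truth$branch_truth
  # losses of duplicate copies do not touch the ancestral ortholog map
  lostA <- intersect(bt$A$losses, om$ancestor)
  lostB <- intersect(union(bt$I$losses, bt$B$losses), om$ancestor)
  lostC <- intersect(union(bt$I$losses, bt$C$losses), om$ancestor)
  expect_equal(sum(is.na(om$A)), length(lostA))
  expect_equal(sum(is.na(om$B)), length(lostB))
  expect_equal(sum(is.na(om$C)), length(lostC))
  expect_equal(sum(stats::complete.cases(om)),
               40 - length(unique(c(lostA, lostB, lostC))))
  # every descendant gene traces to an ancestor, a duplication or a TE
  dup_ids <- unlist(lapply(bt, function(b) b$duplications$new_id))
  for (spn in names(s$genomes)) {
    ids <- sub(paste0("^", spn, "_"), "", s$genomes[[spn]]$genes$gene_id)
    expect_true(all(ids %in% c(om$ancestor, dup_ids)))
  }
})

test_that("RIP strictly shifts the family dinucleotide indices", {
  set.seed(31)
  for (i in 1:10) {
    fam <- triclade:::random_biased_dna(900)
    pre <- rip_indices(dinucleotide_counts(rep(fam, 3)))
    post_seqs <- replicate(3, apply_rip(fam, 2, 0.2)$seq)
    post <- rip_indices(dinucleotide_counts(post_seqs))
    expect_gt(post$ta_at, pre$ta_at)
    expect_lt(post$composite, pre$composite)
  }
})
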