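test_that("dinucleotide counting matches hand counts and sums families", {
  d <- dinucleotide_counts("TATA")
  expect_equal(d$counts[["TA"]], 2L); expect_equal(d$counts[["AT"]], 1L)
  d2 <- dinucleotide_counts("CACATG")
  expect_equal(d2$counts[["CA"]], 2L)
  expect_equal(d2$counts[["AC"]], 1L)
  expect_equal(d2$counts[["AT"]], 1L)
  expect_equal(d2$counts[["TG"]], 1L)
  # family-sum rule
  fam <- dinucleotide_counts(c("CA", "CA"))
  expect_equal(fam$counts[["CA"]], 2L)
  # windows with N are skipped but tallied
  dn <- dinucleotide_counts("CANA")
  expect_equal(sum(dn$counts), 1L)
  expect_equal(dn$skipped, 2L)
  expect_equal(dn$total_windows, 3L)
})

test_that("RIP indices and verdicts follow the threshold rules", {
  r1 <- rip_indices(dinucleotide_counts("TATATT"))
  expect_equal(r1$ta_at, 1.0)
  expect_true(is.na(r1$composite))
  expect_equal(r1$verdict, "indeterminate")
  r2 <- rip_indices(dinucleotide_counts("CACATG"))
  expect_equal(r2$ta_at, 0.0)
  expect_equal(r2$composite, 3.0)
  expect_equal(r2$verdict, "rip_negative")
  # heavy RIP on genome-like sequence forces a positive verdict
  set.seed(2)
  base <- triclade:::random_biased_dna(3000)
  ripped <- apply_rip(base, 2, 0.5)$seq
  r3 <- rip_indices(dinucleotide_counts(ripped))
  expect_gt(r3$ta_at, 0.89); expect_lt(r3$composite, 1.03)
  expect_equal(r3$verdict, "rip_positive")
})

test_that("indices are invariant under reverse complement in both-strand mode", {
  set.seed(6)
  s <- triclade:::random_biased_dna(2000)
  rc <- triclade:::reverse_complement(s)
  i1 <- rip_indices(dinucleotide_counts(s, both_strands = TRUE))
  i2 <- rip_indices(dinucleotide_counts(rc, both_strands = TRUE))
  expect_equal(i1$ta_at, i2$ta_at)
  expect_equal(i1$composite, i2$composite)
})

test_that("the genome profile reduces to sequence indices and tiles windows", {
  g <- genome_annotation("t", c(s1 = "TATATATATA"),
                         data.frame(gene_id = character(0),
                                    scaffold_id = character(0),
                                    start = integer(0), end = integer(0),
                                    strand = character(0), cds = character(0),
                                    protein = character(0)))
  pr <- genome_rip_profile(g, window = 1000, step = 500)
  ref <- rip_indices(dinucleotide_counts("TATATATATA"))
  expect_equal(pr$genome_wide$ta_at, ref$ta_at)
  expect_equal(nrow(pr$track), 0L)  # scaffold shorter than window
  set.seed(3)
  g2 <- genome_annotation("t2",
    c(s1 = triclade:::random_biased_dna(3200)),
    data.frame(gene_id = character(0), scaffold_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               cds = character(0), protein = character(0)))
  pr2 <- genome_rip_profile(g2, window = 1000, step = 500)
  expect_equal(nrow(pr2$track), floor((3200 - 1000) / 500) + 1)
})

test_that("repeat finding instantiates the length/identity/copy criteria", {
  set.seed(44)
  mk_genome <- function(copies, copy_len) {
    el <- triclade:::random_biased_dna(copy_len)
    parts <- character(0)
    for (i in seq_len(copies))
      parts <- c(parts, triclade:::random_biased_dna(700), el)
    parts <- c(parts, triclade:::random_biased_dna(700))
    genome_annotation("r", c(s1 = paste(parts, collapse = "")),
                      data.frame(gene_id = character(0),
                                 scaffold_id = character(0),
                                 start = integer(0), end = integer(0),
                                 strand = character(0), cds = character(0),
                                 protein = character(0)))
  }
  f3 <- find_repeat_families(mk_genome(3, 500))
  expect_equal(length(unique(f3$family_id)), 1L)
  expect_equal(nrow(f3), 3L)
  f2 <- find_repeat_families(mk_genome(2, 500))
  expect_equal(nrow(f2), 0L)
  f300 <- find_repeat_families(mk_genome(3, 300))
  expect_equal(nrow(f300), 0L)
})

test_that("Ti/Tv counting handles hand cases and RIP-only divergence", {
  tt <- alignment_ti_tv(c("AAAA", "GAAC"))
  expect_equal(tt$transitions, 1L)
  expect_equal(tt$transversions, 1L)
  expect_equal(tt$ratio, 1.0)
  same <- alignment_ti_tv(c("ACGT", "ACGT"))
  expect_equal(same$flag, "undefined")
  expect_error(alignment_ti_tv(c("AC", "ACGT")), "equal length")
  set.seed(10)
  fam <- triclade:::random_biased_dna(600)
  copies <- replicate(3, apply_rip(fam, 2, 0.3)$seq)
  rr <- alignment_ti_tv(copies)  # RIP makes only transitions
  expect_equal(rr$flag, "infinite")
  expect_equal(rr$transversions, 0L)
})

test_that("copy curation keeps the most self-similar fraction", {
  set.seed(20)
  fam <- triclade:::random_biased_dna(500)
  close_copies <- replicate(3, apply_rip(fam, 1, 0.1)$seq)
  far <- apply_rip(fam, 6, 0.8)$seq
  kept <- curate_family_copies(c(close_copies, far), q = 0.75)
  expect_equal(length(kept), 3L)
  expect_false(far %in% kept)
})
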