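test_that("RpM matches the definition and columns sum to one million", {
  cm <- toy_count_matrix(matrix(c(50L, 150L, 300L), 3, 1))
  rpm <- compute_rpm(cm)
  expect_equal(unname(rpm[, 1]), c(100000, 300000, 600000))
  expect_equal(sum(rpm[, 1]), 1e6)

  set.seed(311)
  cm2 <- toy_count_matrix(matrix(rpois(50, 40), 10, 5))
  rpm2 <- compute_rpm(cm2)
  expect_equal(unname(colSums(rpm2)), rep(1e6, 5), tolerance = 1e-9)
  expect_equal(attr(rpm2, "unit"), "RpM")

  zero <- toy_count_matrix(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(compute_rpm(zero), "s2")
})

test_that("FPKM matches the definition and is scale invariant per column", {
  # pad library to 1e6 mapped reads via a filler gene
  vals <- toy_counts(matrix(c(100L, 999900L), 2, 1))
  cm <- count_matrix(vals, data.frame(sample_id = "s1", fraction = "global",
                                      condition = "A"))
  lengths <- c(g1 = 2000L, g2 = 1000L)
  fpkm <- compute_fpkm(cm, lengths)
  expect_equal(fpkm["g1", 1], 50)

  set.seed(312)
  vals2 <- toy_counts(matrix(rpois(20, 100), 10, 2))
  lengths2 <- setNames(sample(500:3000, 10), rownames(vals2))
  f1 <- compute_fpkm(vals2, lengths2)
  f2 <- compute_fpkm(vals2 * 3L, lengths2)
  expect_equal(f1, f2)

  expect_error(compute_fpkm(vals2, lengths2[-1]), "length")
})

test_that("the miRNA read cutoff honours the strict 'more than half' rule", {
  vals <- toy_counts(rbind(c(5, 12, 8, 9), c(5, 12, 8, 20), c(0, 0, 0, 0)),
                     genes = c("three_low", "half_low", "all_zero"))
  attr(vals, "unit") <- "RpM"
  rep <- flag_low_mirnas(vals, threshold = 10, sample_fraction = 0.5)
  expect_equal(rep$flag[rep$gene_id == "three_low"], "below_read_cutoff")
  expect_equal(rep$flag[rep$gene_id == "half_low"], "kept")
  expect_equal(rep$flag[rep$gene_id == "all_zero"], "below_read_cutoff")
  # exactly one flag per gene, flags partition the set
  expect_equal(sort(rep$gene_id), sort(rownames(vals)))
  # idempotent: re-flagging the same abundances gives the same report
  expect_identical(flag_low_mirnas(vals), rep)
})

test_that("the mRNA fraction filter honours the strict '<' boundary", {
  # grand total 2,000,000: 15 reads = 7.5e-6 < 1e-5 removed; 20 = 1e-5 kept
  big <- 2000000L - 15L - 20L - 1000L
  cm <- toy_count_matrix(matrix(c(15L, 20L, 1000L, big), 4, 1),
                         genes = c("below", "boundary", "mid", "huge"))
  out <- filter_low_mrnas(cm, 1e-5)
  expect_equal(out$report$flag[out$report$gene_id == "below"], "removed_low_fraction")
  expect_equal(out$report$flag[out$report$gene_id == "boundary"], "kept")
  expect_equal(rownames(out$counts$counts), c("boundary", "mid", "huge"))

  solo <- toy_count_matrix(matrix(123L, 1, 1))
  expect_equal(filter_low_mrnas(solo)$report$flag, "kept")

  # idempotence: filtering the filtered matrix removes nothing further
  again <- filter_low_mrnas(out$counts, 1e-5)
  expect_identical(again$counts$counts, out$counts$counts)
})

test_that("delta-delta-Ct relative expression follows the sign convention", {
  mk <- function(cond, tgt, ref, n = 3) {
    data.frame(sample_id = rep(paste0(cond, seq_len(n)), 2),
               gene_id = rep(c("mir", "U6"), each = n),
               Ct = c(rep(tgt, n), rep(ref, n)),
               condition = cond, stringsAsFactors = FALSE)
  }
  ct <- rbind(mk("P10", 25, 20), mk("adult", 27, 20))
  out <- qpcr_relative_expression(ct, "mir", "U6", "P10")
  expect_equal(out$signed_fold[out$condition == "P10"], 1)
  expect_equal(out$signed_fold[out$condition == "adult"], -4)
  expect_equal(out$rel_expression[out$condition == "adult"], 0.25)

  # antisymmetry: swapping the two delta-Cts flips the fold
  ct2 <- rbind(mk("P10", 27, 20), mk("adult", 25, 20))
  out2 <- qpcr_relative_expression(ct2, "mir", "U6", "P10")
  expect_equal(out2$signed_fold[out2$condition == "adult"], 4)

  missing_ref <- ct[!(ct$gene_id == "U6" & ct$condition == "adult"), ]
  expect_error(qpcr_relative_expression(missing_ref, "mir", "U6", "P10"),
               "reference")
})
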