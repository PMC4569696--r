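test_that("size factors reproduce the median-of-ratios definition", {
  ident <- toy_counts(matrix(rep(c(5L, 9L, 13L), 3), 3, 3))
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3))

  hand <- toy_counts(matrix(c(2L, 4L, 4L, 8L, 6L, 12L), 3, 2, byrow = TRUE))
  expect_equal(unname(estimate_size_factors(hand)), c(0.7071, 1.4142),
               tolerance = 1e-4)

  solo <- toy_counts(matrix(c(3L, 8L), 2, 1))
  expect_equal(unname(estimate_size_factors(solo)), 1)

  all_zero_somewhere <- toy_counts(matrix(c(0L, 5L, 4L, 0L), 2, 2))
  expect_error(estimate_size_factors(all_zero_somewhere), "cannot normalize")
})

test_that("size factors are scale-equivariant and match DESeq2's implementation", {
  set.seed(321)
  # odd number of all-positive genes: the ratio-scale and log-scale medians
  # coincide, so the DESeq2 implementation is directly comparable
  counts <- toy_counts(matrix(rpois(84, 60) + 1L, 21, 4))
  sf <- estimate_size_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  sf2 <- estimate_size_factors(scaled)
  expect_equal(sf2[2], 3 * sf[2] * (sf2[1] / sf[1]), tolerance = 1e-9)

  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("dispersion estimation recovers known truth", {
  set.seed(322)
  n <- 500
  grp <- rep(c("A", "B"), each = 10)
  pois <- toy_counts(matrix(rpois(n * 20, 200), n, 20))
  sf1 <- setNames(rep(1, 20), colnames(pois))
  d_pois <- estimate_dispersions(pois, sf1, grp)
  expect_gt(mean(d_pois$raw_dispersion == 0), 0.4)
  expect_lte(median(d_pois$used_dispersion), 0.02)

  nb <- toy_counts(matrix(rnbinom(n * 20, mu = 200, size = 5), n, 20))
  d_nb <- estimate_dispersions(nb, sf1, grp)
  expect_gt(median(d_nb$raw_dispersion), 0.1)
  expect_lt(median(d_nb$raw_dispersion), 0.3)

  flat <- toy_counts(matrix(7L, 3, 20))
  d_flat <- estimate_dispersions(flat, sf1, grp)
  expect_equal(d_flat$raw_dispersion, rep(0, 3))
})

test_that("identical groups give log2fc 0 and p 1; zero genes are not tested", {
  vals <- toy_counts(cbind(matrix(c(10L, 25L, 0L), 3, 2),
                           matrix(c(10L, 25L, 0L), 3, 2)))
  grp <- rep(c("A", "B"), each = 2)
  sf <- setNames(rep(1, 4), colnames(vals))
  res <- test_differential(vals, sf, 0.1, grp, c("A", "B"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue[1:2], rep(1, 2))
  expect_equal(res$status[3], "not_tested")
  expect_equal(res$pvalue[3], 1)
  expect_true(is.na(res$qvalue[3]))
})

test_that("swapping the contrast negates log2fc and keeps p-values", {
  set.seed(323)
  vals <- toy_counts(matrix(rnbinom(200 * 8, mu = 80, size = 10), 200, 8))
  grp <- rep(c("A", "B"), each = 4)
  sf <- estimate_size_factors(vals)
  disp <- estimate_dispersions(vals, sf, grp)
  ab <- test_differential(vals, sf, disp, grp, c("A", "B"))
  ba <- test_differential(vals, sf, disp, grp, c("B", "A"))
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$pvalue, ab$pvalue)
})

test_that("normal approximation agrees with the exact test near the boundary", {
  set.seed(324)
  vals <- toy_counts(matrix(rnbinom(50 * 8, mu = 600, size = 1 / 0.05), 50, 8))
  grp <- rep(c("A", "B"), each = 4)
  sf <- setNames(rep(1, 8), colnames(vals))
  exact <- test_differential(vals, sf, 0.05, grp, c("A", "B"),
                             exact_limit = 1e9)
  approx <- test_differential(vals, sf, 0.05, grp, c("A", "B"),
                              exact_limit = 1)
  expect_equal(approx$pvalue, exact$pvalue, tolerance = 0.15)
  expect_equal(cor(log10(approx$pvalue + 1e-12), log10(exact$pvalue + 1e-12)),
               1, tolerance = 0.01)
})

test_that("BH adjustment matches hand computation and keeps its bounds", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(325)
  p <- runif(50)
  q <- adjust_bh(p)
  expect_true(all(q >= p & q <= 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the nbde model object composes the pieces and its methods work", {
  set.seed(326)
  vals <- toy_counts(matrix(rnbinom(100 * 8, mu = 100, size = 20), 100, 8))
  fit <- nbde(vals, groups = rep(c("A", "B"), each = 4), contrast = c("A", "B"))
  expect_s3_class(fit, "nbde")
  expect_equal(length(coef(fit)), 100)
  expect_output(print(fit), "vs")
  s <- summary(fit)
  expect_equal(s$n_tested, 100)
  # composition: identical to calling the stages by hand
  sf <- estimate_size_factors(vals)
  disp <- estimate_dispersions(vals, sf, rep(c("A", "B"), each = 4))
  res <- test_differential(vals, sf, disp, rep(c("A", "B"), each = 4),
                           c("A", "B"))
  expect_equal(fit$results, res)
})
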