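test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 77, n_mrnas = 400,
                           n_planted_degradation = 20,
                           n_planted_suppression = 20,
                           n_developmental_de = 40, n_timecourse_pairs = 6,
                           n_mirnas = 30, n_clustered_mirnas = 12)
  a <- generate_paired_fraction_counts(cfg)
  b <- generate_paired_fraction_counts(cfg)
  expect_identical(a$global$counts, b$global$counts)
  expect_identical(a$risc$counts, b$risc$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_timecourse(cfg), generate_timecourse(cfg))
  expect_identical(generate_mirna_annotations(cfg, a$truth),
                   generate_mirna_annotations(cfg, b$truth))

  other <- simulation_config(seed = 78, n_mrnas = 400,
                             n_planted_degradation = 20,
                             n_planted_suppression = 20,
                             n_developmental_de = 40, n_timecourse_pairs = 6,
                             n_mirnas = 30, n_clustered_mirnas = 12)
  expect_false(identical(generate_paired_fraction_counts(other)$global$counts,
                         a$global$counts))
  expect_error(simulation_config(n_mrnas = 10, n_planted_degradation = 20,
                                 seed = 1), "planted")
})

test_that("the default configuration survives the abundance filter nearly intact", {
  cfg <- simulation_config(seed = 21)
  sim <- generate_paired_fraction_counts(cfg)
  kept <- nrow(filter_low_mrnas(sim$global)$counts$counts)
  expect_gte(kept, 4800)
  expect_lte(kept, 5000)
})

test_that("planted truth satisfies downstream contracts", {
  cfg <- simulation_config(seed = 23, n_mrnas = 600,
                           n_planted_degradation = 25,
                           n_planted_suppression = 25,
                           n_developmental_de = 60, n_mirnas = 40,
                           n_clustered_mirnas = 16, n_timecourse_pairs = 6)
  sim <- generate_paired_fraction_counts(cfg)
  truth <- sim$truth
  expect_equal(sum(truth$role == "direct_degradation"), 25)
  expect_equal(sum(truth$role == "direct_suppression"), 25)
  # planted sets disjoint; modes carry the planted sign structure
  expect_true(all(truth$lfc_risc[truth$role != "null"] > 0))
  expect_true(all(truth$lfc_global[truth$role == "direct_degradation"] < 0))
  expect_true(all(truth$lfc_global[truth$role == "direct_suppression"] == 0))

  ann <- generate_mirna_annotations(cfg, truth)
  # every planted target's UTR carries at least one site of its miRNA
  for (i in seq_len(nrow(ann$utrs))) {
    seed7 <- ann$annotations$seed[
      ann$annotations$mirna_id == ann$utrs$mirna_id[i]]
    expect_gte(length(scan_seed_matches(ann$utrs$utr[i], seed7)), 1)
  }
})

test_that("null configurations yield nominal type-I error downstream", {
  cfg <- simulation_config(seed = 29, n_mrnas = 1500,
                           n_planted_degradation = 0,
                           n_planted_suppression = 0,
                           n_developmental_de = 0, n_timecourse_pairs = 5)
  sim <- generate_paired_fraction_counts(cfg)
  fit <- nbde(sim$global, contrast = c("control", "mirOE"))
  frac <- mean(fit$results$pvalue < 0.05)
  # conservative-by-design dispersion sharing: at or below nominal, not far off
  expect_lt(frac, 0.07)
  expect_gt(frac, 0.005)
  expect_lt(sum(!is.na(fit$results$qvalue) & fit$results$qvalue <= 0.1), 10)
})

test_that("null time-course pairs match the closed-form mean absolute correlation", {
  cfg <- simulation_config(seed = 31, r_true = 0, n_timecourse_pairs = 150)
  tc <- generate_timecourse(cfg)
  rs <- mapply(function(mid, tid) correlate_pairs(
    tc$mirna_tc[tc$mirna_tc$feature_id == mid, ],
    tc$mrna_tc[tc$mrna_tc$feature_id == tid, ])$r,
    tc$truth$mirna_id, tc$truth$mrna_id)
  # for n = 6 the null density of r is prop. to (1 - r^2), so E|r| = 3/8
  expect_equal(mean(abs(rs)), 0.375, tolerance = 0.12)
})

test_that("annotation generation plants recoverable family/cluster structure", {
  cfg <- simulation_config(seed = 37, n_mirnas = 80, n_clustered_mirnas = 30)
  ann <- generate_mirna_annotations(cfg)
  got <- group_clusters(group_families(ann$annotations))
  expect_equal(setNames(got$family_id, got$mirna_id), ann$family_truth)
  expect_equal(setNames(got$cluster_id, got$mirna_id), ann$cluster_truth)
  # the planted cross-cluster family makes families coarser than clusters alone
  fam_sizes <- table(got$family_id)
  shared <- names(fam_sizes[fam_sizes >= 2])
  expect_gte(length(shared), 1)
  members <- got[got$family_id %in% shared, ]
  expect_gt(length(unique(members$cluster_id)), 1)

  solo <- generate_mirna_annotations(
    simulation_config(seed = 37, n_mirnas = 1, n_clustered_mirnas = 0))
  got1 <- group_clusters(group_families(solo$annotations))
  expect_equal(got1$family_id, got1$mirna_id)
  expect_equal(got1$cluster_id, got1$mirna_id)
})
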