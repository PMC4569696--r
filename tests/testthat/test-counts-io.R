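test_that("count tables round-trip through TSV exactly, preserving order", {
  set.seed(301)
  vals <- toy_counts(matrix(rpois(60, 25), 10, 6))
  cm <- toy_count_matrix(matrix(rpois(60, 25), 10, 6))
  cm <- count_matrix(vals, cm$sample_meta)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(cm, tsv, sheet)
  back <- load_count_table(tsv, sheet)
  expect_identical(back$counts, cm$counts)
  expect_identical(rownames(back$counts), rownames(cm$counts))
  expect_identical(colnames(back$counts), colnames(cm$counts))
  expect_equal(back$sample_meta$condition, cm$sample_meta$condition)
})

test_that("malformed counts are rejected with the offending cell named", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t3\t0", "g2\t3.5\t7"), tsv)
  writeLines(c("sample_id\tfraction\tcondition",
               "s1\tglobal\tA", "s2\tglobal\tB"), sheet)
  expect_error(load_count_table(tsv, sheet), "g2.*s1|s1.*g2")
  expect_error(count_matrix(toy_counts(c(-1L, 2L)),
                            data.frame(sample_id = "s1", fraction = "global",
                                       condition = "A")),
               "negative")
})

test_that("samples missing from the sheet are a consistency error", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t3\t0"), tsv)
  writeLines(c("sample_id\tfraction\tcondition", "s1\tglobal\tA"), sheet)
  expect_error(load_count_table(tsv, sheet), "absent from sample sheet")
})

test_that("column permutation of the input permutes the matrix accordingly", {
  set.seed(302)
  vals <- toy_counts(matrix(rpois(40, 10), 8, 5))
  meta <- data.frame(sample_id = colnames(vals), fraction = "global",
                     condition = rep(c("A", "B"), length.out = 5))
  perm <- c(3, 1, 5, 2, 4)
  cm1 <- count_matrix(vals, meta)
  cm2 <- count_matrix(vals[, perm], meta)
  expect_identical(cm2$counts, cm1$counts[, perm])
  expect_identical(cm2$sample_meta$sample_id, colnames(vals)[perm])
})

test_that("miRNA annotations match FASTA to GFF3 by id, not order", {
  cfg <- simulation_config(seed = 5, n_mirnas = 5, n_clustered_mirnas = 0)
  ann <- generate_mirna_annotations(cfg)$annotations
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  shuffled <- ann[c(4, 1, 5, 3, 2), ]
  write_mirna_annotation(ann, gff, withr::local_tempfile())
  writeLines(as.vector(rbind(paste0(">", shuffled$mirna_id),
                             shuffled$mature_sequence)), fa)
  loaded <- load_mirna_annotation(gff, fa)
  expect_equal(loaded$mirna_id, ann$mirna_id)
  expect_equal(loaded$mature_sequence, ann$mature_sequence)
  expect_equal(loaded$start, ann$start)
})

test_that("FASTA/GFF3 id mismatches raise a cross-reference error", {
  cfg <- simulation_config(seed = 5, n_mirnas = 2, n_clustered_mirnas = 0)
  ann <- generate_mirna_annotations(cfg)$annotations
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_mirna_annotation(ann, gff, withr::local_tempfile())
  writeLines(c(">syn-mir-001", ann$mature_sequence[1],
               ">not-in-gff", "ACGUACGUACGUACGUACGUAC"), fa)
  expect_error(load_mirna_annotation(gff, fa), "not-in-gff")
})

test_that("results tables round-trip and reject unknown schemas", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- de_row(character(0), numeric(0), numeric(0))
  write_results_table(empty, path)
  expect_equal(nrow(read_results_table(path)), 0)

  set.seed(303)
  recs <- de_row(sprintf("g%03d", 1:100), rnorm(100), runif(100))
  recs$pvalue <- runif(100); recs$mean_A <- rlnorm(100); recs$mean_B <- rlnorm(100)
  write_results_table(recs, path)
  back <- read_results_table(path)
  for (col in c("mean_A", "mean_B", "log2fc", "pvalue", "qvalue"))
    expect_equal(back[[col]], recs[[col]], tolerance = 1e-6)
  expect_identical(back$gene_id, recs$gene_id)

  expect_error(write_results_table(data.frame(a = 1, b = 2), path),
               "schema")
})
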