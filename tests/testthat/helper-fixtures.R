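# Small in-code fixtures shared across test files.

toy_counts <- function(vals, genes = NULL, samples = NULL) {
  n <- if (is.matrix(vals)) nrow(vals) else length(vals)
  m <- if (is.matrix(vals)) ncol(vals) else 1L
  vals <- matrix(vals, n, m)
  rownames(vals) <- genes %||% paste0("g", seq_len(n))
  colnames(vals) <- samples %||% paste0("s", seq_len(m))
  vals
}

toy_count_matrix <- function(vals, fraction = "global", condition = NULL, ...) {
  vals <- toy_counts(vals, ...)
  condition <- condition %||% rep(c("A", "B"), length.out = ncol(vals))
  count_matrix(vals, data.frame(sample_id = colnames(vals),
                                fraction = fraction, condition = condition,
                                stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long-format single-feature time course
toy_timecourse <- function(id, means, timepoints, nrep = 4, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(feature_id = id,
             timepoint = rep(timepoints, each = nrep),
             replicate = rep(seq_len(nrep), length(timepoints)),
             value = rep(means, each = nrep) + rnorm(length(means) * nrep, 0, sd),
             stringsAsFactors = FALSE)
}

# Independent brute-force median-of-ratios (per-sample loop, no shared code).
brute_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- apply(counts[keep, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(counts)), function(j)
    median(counts[keep, j] / ref), numeric(1))
}

# Independent BH step-up by enumeration over candidate thresholds.
brute_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

de_row <- function(gene_id, log2fc, qvalue) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, mean_A = rep(1, n), mean_B = rep(1, n),
             log2fc = log2fc, pvalue = qvalue, qvalue = qvalue,
             status = rep("unchanged", n), stringsAsFactors = FALSE)
}
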