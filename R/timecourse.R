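#' Correlate a miRNA and a candidate-target mRNA across a time course
#'
#' Time courses are long-format data.frames with columns `feature_id`,
#' `timepoint`, `replicate`, `value` and a shared, ordered timepoint grid.
#' With `pairing = "per-timepoint-mean"` (default) replicate values are
#' averaged within timepoints before correlating the two trajectories, the
#' group-level reading used for postnatal miRNA/target comparisons. With
#' `pairing = "per-animal"` observations are matched by timepoint and
#' replicate id.
#'
#' @param mirna_tc,mrna_tc single-feature time courses (long format).
#' @param pairing `"per-timepoint-mean"` or `"per-animal"`.
#' @param method `"pearson"` (default; two-sided p from the t-distribution
#'   with n-2 df) or `"spearman"`.
#' @return data.frame `mirna_id`, `mrna_id`, `r`, `pvalue`, `n`.
#' @export
correlate_pairs <- function(mirna_tc, mrna_tc,
                            pairing = c("per-timepoint-mean", "per-animal"),
                            method = c("pearson", "spearman")) {
  pairing <- match.arg(pairing)
  method <- match.arg(method)
  shared <- intersect(unique(mirna_tc$timepoint), unique(mrna_tc$timepoint))
  if (length(shared) == 0) stop("no shared timepoints", call. = FALSE)
  a <- mirna_tc[mirna_tc$timepoint %in% shared, ]
  b <- mrna_tc[mrna_tc$timepoint %in% shared, ]
  if (pairing == "per-timepoint-mean") {
    x <- tapply(a$value, factor(a$timepoint, levels = shared), mean)
    y <- tapply(b$value, factor(b$timepoint, levels = shared), mean)
  } else {
    key_a <- paste(a$timepoint, a$replicate)
    key_b <- paste(b$timepoint, b$replicate)
    shared_keys <- intersect(key_a, key_b)
    if (!length(shared_keys))
      stop("per-animal pairing requires matched replicate ids", call. = FALSE)
    x <- a$value[match(shared_keys, key_a)]
    y <- b$value[match(shared_keys, key_b)]
  }
  n <- length(x)
  if (n < 3) stop("fewer than 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series; correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(as.numeric(x), as.numeric(y), method = method,
                        alternative = "two.sided", exact = FALSE)
  data.frame(mirna_id = mirna_tc$feature_id[1L],
             mrna_id = mrna_tc$feature_id[1L],
             r = unname(ct$estimate), pvalue = ct$p.value, n = n,
             stringsAsFactors = FALSE)
}

#' Earliest timepoint at which expression departs from a reference
#'
#' Each non-reference timepoint is compared against the reference with a
#' Welch two-sample t-test; p-values are Bonferroni-corrected across the
#' non-reference timepoints, and the earliest significant timepoint (in grid
#' order) is returned. This is a descriptive change-point locator standing in
#' for a one-way ANOVA with a Dunnett post-hoc comparison; exact Dunnett
#' critical values are deliberately not reproduced.
#'
#' @param tc single-feature long-format time course; `timepoint` must be a
#'   factor or will be ordered by first appearance.
#' @param reference_timepoint label of the reference (e.g. `"P10"`).
#' @param alpha family-wise level (default 0.05). Looser alpha never yields a
#'   later change-point.
#' @return The earliest significant timepoint label, or `NA_character_` when
#'   none passes. Timepoints with fewer than 2 replicates are excluded with a
#'   warning.
#' @export
earliest_change_timepoint <- function(tc, reference_timepoint, alpha = 0.05) {
  levels <- if (is.factor(tc$timepoint)) levels(tc$timepoint) else unique(tc$timepoint)
  if (!reference_timepoint %in% levels)
    stop("reference timepoint '", reference_timepoint, "' absent", call. = FALSE)
  ref <- tc$value[tc$timepoint == reference_timepoint]
  if (length(ref) < 2)
    stop("reference timepoint needs >= 2 replicates", call. = FALSE)
  others <- setdiff(levels, reference_timepoint)
  usable <- others[vapply(others, function(tp)
    sum(tc$timepoint == tp) >= 2L, logical(1))]
  if (length(usable) < length(others))
    warning("timepoint(s) with a single replicate excluded: ",
            paste(setdiff(others, usable), collapse = ", "))
  if (!length(usable)) return(NA_character_)
  m <- length(usable)
  for (tp in usable) {
    vals <- tc$value[tc$timepoint == tp]
    p <- tryCatch(stats::t.test(vals, ref)$p.value, error = function(e) 1)
    if (is.finite(p) && p <= alpha / m) return(tp)
  }
  NA_character_
}
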