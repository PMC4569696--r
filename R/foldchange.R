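#' Signed linear fold change between two log2 group means
#'
#' Computes `r = 2^(alt - ref)` and reports `+r` when `r >= 1` and `-1/r`
#' otherwise, the negative-reciprocal convention of microarray fold-change
#' tables (a value of -4.2 means 4.2-fold lower in the alternative group).
#' Antisymmetric: swapping the arguments flips the sign.
#'
#' @param mean_log2_ref,mean_log2_alt finite log2 group means (vectorised).
#' @return Signed fold(s); `|signed fold| >= 1`, equality gives `+1`.
#' @export
signed_fold_change <- function(mean_log2_ref, mean_log2_alt) {
  if (any(!is.finite(mean_log2_ref)) || any(!is.finite(mean_log2_alt)))
    stop("log2 means must be finite", call. = FALSE)
  d <- mean_log2_alt - mean_log2_ref
  ifelse(d >= 0, 2^d, -(2^-d))
}

#' Round half away from zero
#'
#' Display rounding used for fold-change tables (`round()` in R rounds half
#' to even, which would not reproduce printed table values).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Select features changed beyond a fold threshold at an FDR
#'
#' Selection rule: `|signed_fc| >= fc_threshold` and `qvalue <= q_threshold`
#' (both boundaries inclusive).
#'
#' @param records data.frame with columns `feature_id`, `signed_fc`, `qvalue`.
#' @param fc_threshold minimum absolute fold (default 2).
#' @param q_threshold maximum adjusted p (default 0.05).
#' @return list with `selected` (subset of `records`), `n_up`, `n_down`.
#' @export
select_changed <- function(records, fc_threshold = 2, q_threshold = 0.05) {
  stopifnot(fc_threshold > 0, q_threshold > 0)
  need <- c("feature_id", "signed_fc", "qvalue")
  if (!all(need %in% names(records)) || anyNA(records$qvalue))
    stop("records need feature_id, signed_fc and a qvalue for every row",
         call. = FALSE)
  sel <- abs(records$signed_fc) >= fc_threshold & records$qvalue <= q_threshold
  selected <- records[sel, , drop = FALSE]
  list(selected = selected,
       n_up = sum(selected$signed_fc > 0),
       n_down = sum(selected$signed_fc < 0))
}

#' Load the packaged microarray fold-change reference table
#'
#' Seventeen selected miRNAs with their printed adult-vs-P10 fold change,
#' BH-adjusted p-value and the mean log2 microarray abundance of each group.
#'
#' @return data.frame with columns `mirna`, `fold_change_adult_vs_p10`,
#'   `adjusted_p`, `mean_p10_log2`, `mean_adult_log2`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_mirnas.tsv", package = "riscmir")
  if (path == "")
    stop("packaged fixture table1_mirnas.tsv is missing", call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute the reference fold changes from their log2 means
#'
#' For each row of the packaged table, the signed fold is recomputed from the
#' two printed log2 means and compared with the printed fold: `pass` requires
#' agreement within `tolerance` (printed means are rounded to two decimals,
#' which can shift the last digit of large folds); `exact_one_decimal` marks
#' rows whose recomputed fold, rounded half-away-from-zero to one decimal,
#' equals the printed value.
#'
#' @param tolerance absolute fold tolerance for `pass` (default 0.1).
#' @return data.frame `mirna`, `printed_fold`, `recomputed_fold`,
#'   `exact_one_decimal`, `pass`.
#' @export
check_table1_fixture <- function(tolerance = 0.1) {
  tab <- load_table1_fixture()
  recomputed <- signed_fold_change(tab$mean_p10_log2, tab$mean_adult_log2)
  rounded <- round_half_away(recomputed, 1)
  data.frame(
    mirna = tab$mirna,
    printed_fold = tab$fold_change_adult_vs_p10,
    recomputed_fold = recomputed,
    exact_one_decimal = rounded == tab$fold_change_adult_vs_p10,
    pass = abs(recomputed - tab$fold_change_adult_vs_p10) <= tolerance + 1e-9,
    stringsAsFactors = FALSE
  )
}
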