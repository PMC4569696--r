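#' Classify direct miRNA targets from paired RISC and global DE results
#'
#' A gene is called a direct target when its abundance increases
#' significantly in the Ago2 immunoprecipitate (RISC fraction):
#' `risc_q <= fdr` and `risc_log2fc > min_risc_lfc`. The mode of regulation
#' follows the global fraction: a parallel significant decrease
#' (`global_q <= fdr`, `global_log2fc < 0`) indicates RISC-mediated
#' transcript degradation; no significant global change (`global_q > fdr`)
#' indicates translational suppression. A significant global *increase*
#' matches neither admissible outcome and the gene is excluded from the call
#' set with a reason code (returned in the `excluded` element).
#'
#' Calls are monotone in `fdr`: tightening the threshold can only shrink the
#' call set.
#'
#' @param risc_de,global_de per-gene DE tables from [test_differential()] for
#'   the RISC and global fractions; they must cover the same gene universe
#'   (genes passing detection filters in both fractions).
#' @param fdr BH threshold for both fractions (default 0.1).
#' @param min_risc_lfc minimum RISC log2 fold change beyond significance
#'   (default 0, i.e. any significant increase).
#' @return list with `calls` (data.frame `gene_id`, `mode`, `risc_log2fc`,
#'   `risc_q`, `global_log2fc`, `global_q`, sorted by `risc_q`) and
#'   `excluded` (genes meeting the RISC criterion but significantly up
#'   globally, with `reason`).
#' @export
classify_direct_targets <- function(risc_de, global_de, fdr = 0.1,
                                    min_risc_lfc = 0) {
  if (!setequal(risc_de$gene_id, global_de$gene_id))
    stop("RISC and global DE tables must cover the same gene universe; ",
         length(setdiff(risc_de$gene_id, global_de$gene_id)), " / ",
         length(setdiff(global_de$gene_id, risc_de$gene_id)),
         " ids unmatched", call. = FALSE)
  gd <- global_de[match(risc_de$gene_id, global_de$gene_id), ]
  risc_sig <- !is.na(risc_de$qvalue) & risc_de$qvalue <= fdr &
    risc_de$log2fc > min_risc_lfc
  global_down <- !is.na(gd$qvalue) & gd$qvalue <= fdr & gd$log2fc < 0
  global_up <- !is.na(gd$qvalue) & gd$qvalue <= fdr & gd$log2fc >= 0
  global_ns <- is.na(gd$qvalue) | gd$qvalue > fdr

  mk <- function(sel, mode) {
    data.frame(gene_id = risc_de$gene_id[sel],
               mode = rep(mode, sum(sel)),
               risc_log2fc = risc_de$log2fc[sel],
               risc_q = risc_de$qvalue[sel],
               global_log2fc = gd$log2fc[sel],
               global_q = gd$qvalue[sel],
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk(risc_sig & global_down, "degradation"),
                 mk(risc_sig & global_ns, "translational_suppression"))
  calls <- calls[order(calls$risc_q, calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  excluded <- mk(risc_sig & global_up, "excluded")
  excluded$mode <- NULL
  excluded$reason <- rep("significant_global_increase", nrow(excluded))
  list(calls = calls, excluded = excluded)
}

#' Concordance of perturbation-responsive mRNAs with a developmental contrast
#'
#' Each responsive gene (significant in the perturbation contrast) is
#' compared by direction of change with the developmental (adult vs P10)
#' contrast: opposite direction and developmentally significant
#' (`developmental_q <= fdr`) is `opposite_significant`; opposite direction
#' without developmental significance is `opposite_nonsignificant`; same
#' direction is `concordant`. Direction is the sign of `log2fc` regardless of
#' magnitude.
#'
#' @param responsive DE table restricted to perturbation-responsive genes
#'   (caller applies the `q <= fdr` cut); all genes must be present in
#'   `developmental`.
#' @param developmental DE table for the developmental contrast.
#' @param fdr developmental significance threshold (default 0.1).
#' @return list with `records` (per-gene `gene_id`,
#'   `perturbation_direction`, `developmental_direction`, `developmental_q`,
#'   `class`) and `summary` (class `concordance_summary`: counts and
#'   percentages over the responsive set; percentages are `NA` when the
#'   responsive set is empty).
#' @export
concordance_with_development <- function(responsive, developmental, fdr = 0.1) {
  missing_ids <- setdiff(responsive$gene_id, developmental$gene_id)
  if (length(missing_ids))
    stop("responsive gene(s) absent from the developmental contrast: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  dev <- developmental[match(responsive$gene_id, developmental$gene_id), ]
  pdir <- ifelse(responsive$log2fc > 0, "up", "down")
  ddir <- ifelse(dev$log2fc > 0, "up", "down")
  opposite <- pdir != ddir
  dev_sig <- !is.na(dev$qvalue) & dev$qvalue <= fdr
  cls <- ifelse(opposite & dev_sig, "opposite_significant",
                ifelse(opposite, "opposite_nonsignificant", "concordant"))
  records <- data.frame(
    gene_id = responsive$gene_id,
    perturbation_direction = pdir,
    developmental_direction = ddir,
    developmental_q = dev$qvalue,
    class = cls,
    stringsAsFactors = FALSE
  )
  n <- nrow(records)
  counts <- c(
    n_responsive = n,
    n_opposite_significant = sum(cls == "opposite_significant"),
    n_opposite_nonsignificant = sum(cls == "opposite_nonsignificant"),
    n_concordant = sum(cls == "concordant")
  )
  pct <- if (n > 0) round(100 * counts[-1L] / n) else rep(NA_real_, 3L)
  names(pct) <- sub("^n_", "pct_", names(counts)[-1L])
  summary <- structure(as.list(c(counts, pct)), class = "concordance_summary")
  list(records = records, summary = summary)
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("%d responsive mRNAs: %d (%s%%) opposite & significant, %d (%s%%) opposite & not significant, %d (%s%%) concordant\n",
              x$n_responsive,
              x$n_opposite_significant, format(x$pct_opposite_significant),
              x$n_opposite_nonsignificant, format(x$pct_opposite_nonsignificant),
              x$n_concordant, format(x$pct_concordant)))
  invisible(x)
}
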