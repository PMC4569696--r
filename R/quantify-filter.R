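#' Reads-per-million (RpM) abundance for miRNA counts
#'
#' RpM scales each sample's counts to reads per million reads mapped to
#' miRNAs: `rpm[g, s] = counts[g, s] / colsum(s) * 1e6`. Columns with reads
#' therefore sum to exactly one million.
#'
#' @param cm [count_matrix()] restricted to miRNAs.
#' @return Numeric matrix with attribute `unit = "RpM"`.
#' @export
compute_rpm <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("degenerate library (zero total reads) in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  out <- sweep(counts, 2L, totals, "/") * 1e6
  attr(out, "unit") <- "RpM"
  out
}

#' FPKM abundance for mRNA counts
#'
#' Fragments per kilobase of exon per million mapped reads:
#' `fpkm[g, s] = counts[g, s] / (length_kb(g) * colsum(s) / 1e6)`. FPKM is
#' invariant to uniform scaling of a sample's counts.
#'
#' @param cm [count_matrix()] restricted to mRNAs.
#' @param lengths named vector of exonic lengths in bp covering every gene.
#' @return Numeric matrix with attribute `unit = "FPKM"`.
#' @export
compute_fpkm <- function(cm, lengths) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stop("no exonic length for gene(s): ",
         paste(utils::head(missing_len, 5L), collapse = ", "), call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("degenerate library (zero total reads) in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  len_kb <- lengths[rownames(counts)] / 1e3
  out <- sweep(counts / len_kb, 2L, totals / 1e6, "/")
  attr(out, "unit") <- "FPKM"
  out
}

#' Flag low-abundance miRNAs ("below read cutoff")
#'
#' A miRNA is flagged when strictly more than `sample_fraction` of samples
#' have abundance strictly below `threshold` RpM. Flagging is report-driven:
#' no rows are removed.
#'
#' @param abund RpM matrix from [compute_rpm()].
#' @param threshold RpM cutoff (default 10).
#' @param sample_fraction fraction of samples that must be below the cutoff
#'   (default 0.5; the rule is "more than", so exactly half keeps the gene).
#' @return data.frame `gene_id`, `flag` (`kept` / `below_read_cutoff`),
#'   `statistic` (fraction of samples below the cutoff).
#' @export
flag_low_mirnas <- function(abund, threshold = 10, sample_fraction = 0.5) {
  unit <- attr(abund, "unit")
  if (!is.null(unit) && unit != "RpM")
    stop("flag_low_mirnas expects RpM abundances, got ", unit, call. = FALSE)
  frac_below <- rowMeans(abund < threshold)
  data.frame(
    gene_id = rownames(abund),
    flag = ifelse(frac_below > sample_fraction, "below_read_cutoff", "kept"),
    statistic = unname(frac_below),
    stringsAsFactors = FALSE
  )
}

#' Remove mRNAs carrying less than a fraction of all reads
#'
#' A gene is removed when its reads summed over all samples are strictly less
#' than `fraction_threshold` of the grand total (default 1/100,000). Exactly
#' the threshold keeps the gene. Row order of kept genes is preserved.
#'
#' @param cm [count_matrix()] of mRNA counts.
#' @param fraction_threshold minimum share of the grand total (default 1e-5).
#' @return list with `counts` (filtered [count_matrix()]) and `report`
#'   (data.frame `gene_id`, `flag` in `kept` / `removed_low_fraction`,
#'   `statistic` = gene total / grand total).
#' @export
filter_low_mrnas <- function(cm, fraction_threshold = 1e-5) {
  stopifnot(inherits(cm, "count_matrix"))
  grand <- sum(as.numeric(cm$counts))
  if (grand == 0) stop("grand total of counts is zero; nothing to filter", call. = FALSE)
  frac <- rowSums(cm$counts) / grand
  removed <- frac < fraction_threshold
  report <- data.frame(
    gene_id = rownames(cm$counts),
    flag = ifelse(removed, "removed_low_fraction", "kept"),
    statistic = unname(frac),
    stringsAsFactors = FALSE
  )
  kept <- count_matrix(cm$counts[!removed, , drop = FALSE], cm$sample_meta)
  list(counts = kept, report = report)
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Within each condition, Ct values are averaged per gene (arithmetic mean),
#' `dCt = mean Ct(target) - mean Ct(reference)`, and relative expression
#' against the baseline condition is `2^-(dCt_cond - dCt_baseline)`. The
#' result is reported as a signed fold: `+r` when `r >= 1`, `-1/r` otherwise.
#'
#' @param ct data.frame with columns `sample_id`, `gene_id`, `Ct`, `condition`.
#' @param target_gene,reference_gene gene ids; the reference (e.g. U6 or 18S)
#'   must be measured in every sample.
#' @param baseline_condition condition against which folds are expressed.
#' @return data.frame `condition`, `delta_ct`, `rel_expression`, `signed_fold`.
#' @export
qpcr_relative_expression <- function(ct, target_gene, reference_gene,
                                     baseline_condition) {
  need <- c("sample_id", "gene_id", "Ct", "condition")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ct$Ct))) stop("non-finite Ct values", call. = FALSE)
  samples <- unique(ct$sample_id)
  with_ref <- unique(ct$sample_id[ct$gene_id == reference_gene])
  missing_ref <- setdiff(samples, with_ref)
  if (length(missing_ref))
    stop("reference gene '", reference_gene, "' not measured in sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  if (!baseline_condition %in% ct$condition)
    stop("baseline condition '", baseline_condition, "' absent", call. = FALSE)
  mean_ct <- function(gene, cond)
    mean(ct$Ct[ct$gene_id == gene & ct$condition == cond])
  conditions <- unique(ct$condition)
  dct <- vapply(conditions, function(cond)
    mean_ct(target_gene, cond) - mean_ct(reference_gene, cond), numeric(1))
  if (anyNA(dct))
    stop("target gene '", target_gene, "' missing in some condition", call. = FALSE)
  rel <- 2^-(dct - dct[[baseline_condition]])
  data.frame(
    condition = conditions,
    delta_ct = unname(dct),
    rel_expression = unname(rel),
    signed_fold = ifelse(rel >= 1, rel, -1 / rel),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
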