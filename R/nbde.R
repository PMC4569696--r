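#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with strictly positive counts in every sample) of the ratio of the
#' gene's count to its geometric mean across samples. Size factors are
#' scale-equivariant: multiplying one column by `c` multiplies its factor
#' by `c`.
#'
#' @param cm [count_matrix()] or integer matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("cannot normalize: no gene has positive counts in every sample",
         call. = FALSE)
  ref <- counts[all_pos, , drop = FALSE]
  gm <- exp(rowMeans(log(ref)))
  # arithmetic median of the count/geometric-mean ratios (ties averaged on
  # the ratio scale)
  sf <- apply(sweep(ref, 1L, gm, "/"), 2L, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion estimates with a fitted trend
#'
#' Per gene, normalized counts `x = k / s` are pooled across the two groups:
#' the within-group variance `v` (replicated groups only) is compared with the
#' shot-noise expectation `m * mean(1/s)` at base mean `m`, giving the raw
#' dispersion `max(0, (v - m * mean(1/s)) / m^2)` of the NB variance function
#' `Var = mu + alpha * mu^2`. A mean-dispersion trend
#' `alpha(m) = a1 + a0 / m` is fitted by gamma-family regression on genes with
#' positive raw dispersion, and the working dispersion is the conservative
#' per-gene maximum of raw and fitted values.
#'
#' @param cm [count_matrix()] or integer matrix.
#' @param size_factors from [estimate_size_factors()].
#' @param groups factor/character vector of group labels per sample.
#' @return data.frame `gene_id`, `raw_dispersion`, `fitted_dispersion`,
#'   `used_dispersion` (`= pmax(raw, fitted)`).
#' @export
estimate_dispersions <- function(cm, size_factors, groups) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts), length(size_factors) == ncol(counts))
  replicated <- names(which(table(groups) >= 2L))
  if (!length(replicated))
    stop("no group has replicates; dispersion cannot be estimated from the ",
         "data (a blind/pooled design needs an explicit opt-in)", call. = FALSE)
  if (length(setdiff(unique(groups), replicated)))
    warning("group(s) without replicates contribute no variance information")
  use <- groups %in% replicated
  x <- sweep(counts, 2L, size_factors, "/")
  xs <- x[, use, drop = FALSE]
  g <- groups[use]
  m <- rowMeans(xs)
  # pooled within-group variance
  ss <- numeric(nrow(xs))
  df <- 0L
  for (grp in replicated) {
    cols <- which(g == grp)
    gm <- rowMeans(xs[, cols, drop = FALSE])
    ss <- ss + rowSums((xs[, cols, drop = FALSE] - gm)^2)
    df <- df + length(cols) - 1L
  }
  v <- ss / df
  xi <- mean(1 / size_factors[use])
  raw <- ifelse(m > 0, pmax(0, (v - xi * m) / m^2), 0)
  fitted <- fit_dispersion_trend(m, raw)
  data.frame(
    gene_id = rownames(counts),
    raw_dispersion = unname(raw),
    fitted_dispersion = unname(fitted),
    used_dispersion = unname(pmax(raw, fitted)),
    stringsAsFactors = FALSE
  )
}

# Parametric trend alpha(m) = a1 + a0/m via gamma-family GLM on genes with
# positive raw dispersion; falls back to the median positive dispersion when
# the fit is degenerate (few usable genes, non-positive coefficients).
fit_dispersion_trend <- function(m, raw) {
  usable <- m > 0 & raw > 1e-8
  floor_disp <- 1e-8
  fallback <- if (any(usable)) stats::median(raw[usable]) else floor_disp
  if (sum(usable) >= 10L) {
    fit <- tryCatch(
      stats::glm(raw[usable] ~ I(1 / m[usable]),
                 family = stats::Gamma(link = "identity"),
                 start = c(fallback, 1)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      if (all(is.finite(co)) && co[1L] > 0 && co[2L] >= 0) {
        pred <- co[1L] + co[2L] / pmax(m, 1e-8)
        return(pmax(pred, floor_disp))
      }
    }
  }
  rep(pmax(fallback, floor_disp), length(m))
}

#' Exact-style NB test for a two-group contrast
#'
#' For each gene the observed count sums `(kA, kB)` of the two groups are
#' compared under the null hypothesis of a common expression strength: the
#' pooled normalized mean is scaled by each group's summed size factors, the
#' group sums are modelled as negative binomial with the gene's working
#' dispersion, and the two-sided p-value is the total probability of all
#' splits `a + b = kA + kB` no more likely than the observed one, conditioned
#' on the total. When the total exceeds `exact_limit` the conditional
#' distribution is replaced by its normal approximation (conditional mean and
#' variance from the joint normal of the two sums), with continuity
#' correction.
#'
#' Log2 fold changes are `log2((mean_B + pseudocount)/(mean_A + pseudocount))`
#' on normalized group means. Genes with zero counts in both groups are
#' returned with `status = "not_tested"` and p reported as 1 (q as `NA`).
#'
#' @param cm [count_matrix()] or integer matrix.
#' @param size_factors from [estimate_size_factors()].
#' @param dispersions data.frame from [estimate_dispersions()] (column
#'   `used_dispersion`), or a single numeric dispersion applied to all genes.
#' @param groups group label per sample.
#' @param contrast length-2 character `c(A, B)`; positive `log2fc` means
#'   higher in `B`.
#' @param pseudocount added to normalized means before the log ratio
#'   (default 0.5).
#' @param fdr BH threshold used only to label `status` (default 0.1).
#' @param exact_limit count-sum ceiling for the exact conditional sum
#'   (default 5000).
#' @return data.frame of per-gene results: `gene_id`, `mean_A`, `mean_B`,
#'   `log2fc`, `pvalue`, `qvalue`, `status`.
#' @export
test_differential <- function(cm, size_factors, dispersions, groups,
                              contrast, pseudocount = 0.5, fdr = 0.1,
                              exact_limit = 5000) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  groups <- as.character(groups)
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% groups))
    stop("contrast group(s) absent from `groups`: ",
         paste(setdiff(contrast, groups), collapse = ", "), call. = FALSE)
  alpha <- if (is.data.frame(dispersions)) {
    stats::setNames(dispersions$used_dispersion, dispersions$gene_id)[rownames(counts)]
  } else rep(dispersions, nrow(counts))
  if (anyNA(alpha)) stop("missing dispersion for some genes", call. = FALSE)

  selA <- groups == contrast[1L]
  selB <- groups == contrast[2L]
  sfA <- size_factors[selA]; sfB <- size_factors[selB]
  cntA <- counts[, selA, drop = FALSE]; cntB <- counts[, selB, drop = FALSE]
  meanA <- rowMeans(sweep(cntA, 2L, sfA, "/"))
  meanB <- rowMeans(sweep(cntB, 2L, sfB, "/"))
  kA <- rowSums(cntA); kB <- rowSums(cntB)
  # pooled expression strength per gene over the two contrast groups
  qhat <- rowMeans(sweep(counts[, selA | selB, drop = FALSE], 2L,
                         size_factors[selA | selB], "/"))
  SA <- sum(sfA); SB <- sum(sfB)
  S2A <- sum(sfA^2); S2B <- sum(sfB^2)

  n <- nrow(counts)
  pval <- numeric(n)
  for (i in seq_len(n)) {
    pval[i] <- nb_exact_pval(kA[i], kB[i], qhat[i], alpha[i],
                             SA, SB, S2A, S2B, exact_limit)
  }
  tested <- kA + kB > 0
  pval[!tested] <- 1
  qval <- rep(NA_real_, n)
  qval[tested] <- adjust_bh(pval[tested])
  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))
  status <- rep("unchanged", n)
  status[tested & !is.na(qval) & qval <= fdr & log2fc > 0] <- "up"
  status[tested & !is.na(qval) & qval <= fdr & log2fc < 0] <- "down"
  status[!tested] <- "not_tested"
  data.frame(
    gene_id = rownames(counts),
    mean_A = unname(meanA), mean_B = unname(meanB),
    log2fc = unname(log2fc),
    pvalue = unname(pval), qvalue = unname(qval),
    status = status,
    stringsAsFactors = FALSE
  )
}

# Two-sided p for one gene. Group sums are NB with mu = qhat * S and
# Var = mu + alpha * qhat^2 * S2 (sum over samples of per-sample NB variances).
nb_exact_pval <- function(kA, kB, qhat, alpha, SA, SB, S2A, S2B, exact_limit) {
  kS <- kA + kB
  if (kS == 0 || qhat <= 0) return(1)
  muA <- qhat * SA; muB <- qhat * SB
  exvarA <- alpha * qhat^2 * S2A
  exvarB <- alpha * qhat^2 * S2B
  if (kS > exact_limit) {
    vA <- muA + exvarA; vB <- muB + exvarB
    mc <- muA + vA / (vA + vB) * (kS - muA - muB)
    sc <- sqrt(vA * vB / (vA + vB))
    p <- 2 * min(stats::pnorm(kA + 0.5, mc, sc),
                 stats::pnorm(kA - 0.5, mc, sc, lower.tail = FALSE))
    return(min(1, max(p, .Machine$double.xmin)))
  }
  a <- 0:kS
  dens <- function(x, mu, exvar) {
    if (exvar <= 0) stats::dpois(x, mu) else stats::dnbinom(x, mu = mu, size = mu^2 / exvar)
  }
  pa <- dens(a, muA, exvarA)
  pb <- dens(kS - a, muB, exvarB)
  pab <- pa * pb
  total <- sum(pab)
  if (total <= 0) return(1)
  pobs <- pab[kA + 1L]
  min(1, sum(pab[pab <= pobs * (1 + 1e-7)]) / total)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement; input order is preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Fit a two-group negative-binomial differential expression model
#'
#' Convenience front end composing [estimate_size_factors()],
#' [estimate_dispersions()] and [test_differential()] into a classed model
#' object.
#'
#' @inheritParams test_differential
#' @param groups group label per sample; defaults to the `condition` column of
#'   the sample metadata when `cm` is a [count_matrix()].
#' @param dispersions optional; estimated from the data when `NULL`.
#' @param size_factors optional; estimated when `NULL`.
#' @return Object of class `nbde` with elements `results` (the per-gene
#'   table), `size_factors`, `dispersions`, `contrast`, `fdr`.
#' @examples
#' cm <- matrix(rnbinom(400, mu = 50, size = 10), 50, 8,
#'              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
#' fit <- nbde(cm, groups = rep(c("A", "B"), each = 4), contrast = c("A", "B"))
#' summary(fit)
#' @export
nbde <- function(cm, groups = NULL, contrast, size_factors = NULL,
                 dispersions = NULL, pseudocount = 0.5, fdr = 0.1,
                 exact_limit = 5000) {
  if (is.null(groups)) {
    if (!inherits(cm, "count_matrix"))
      stop("`groups` must be given when `cm` is a bare matrix", call. = FALSE)
    groups <- cm$sample_meta$condition
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(cm)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(cm, size_factors, groups)
  res <- test_differential(cm, size_factors, dispersions, groups, contrast,
                           pseudocount = pseudocount, fdr = fdr,
                           exact_limit = exact_limit)
  structure(list(results = res, size_factors = size_factors,
                 dispersions = dispersions, contrast = contrast, fdr = fdr),
            class = "nbde")
}

#' @export
print.nbde <- function(x, ...) {
  cat(sprintf("Negative-binomial differential expression: %s vs %s\n",
              x$contrast[2L], x$contrast[1L]))
  n <- table(factor(x$results$status, c("up", "down", "unchanged", "not_tested")))
  cat(sprintf("%d genes tested; at FDR %.2g: %d up, %d down\n",
              sum(x$results$status != "not_tested"), x$fdr, n[["up"]], n[["down"]]))
  invisible(x)
}

#' @method summary nbde
#' @export
summary.nbde <- function(object, ...) {
  res <- object$results
  out <- list(
    contrast = object$contrast,
    n_tested = sum(res$status != "not_tested"),
    n_up = sum(res$status == "up"),
    n_down = sum(res$status == "down"),
    fdr = object$fdr,
    size_factors = object$size_factors,
    median_dispersion = stats::median(object$dispersions$used_dispersion)
  )
  class(out) <- "summary.nbde"
  out
}

#' @export
print.summary.nbde <- function(x, ...) {
  cat(sprintf("Contrast %s vs %s: %d tested, %d up / %d down at FDR %.2g\n",
              x$contrast[2L], x$contrast[1L], x$n_tested, x$n_up, x$n_down, x$fdr))
  cat("size factors:\n"); print(round(x$size_factors, 4))
  cat(sprintf("median working dispersion: %.4g\n", x$median_dispersion))
  invisible(x)
}

#' @method coef nbde
#' @export
coef.nbde <- function(object, ...) {
  stats::setNames(object$results$log2fc, object$results$gene_id)
}

#' MA plot of an `nbde` fit
#'
#' @param x an `nbde` object.
#' @param ... passed to [graphics::plot()].
#' @method plot nbde
#' @export
plot.nbde <- function(x, ...) {
  res <- x$results
  base_mean <- (res$mean_A + res$mean_B) / 2
  sig <- !is.na(res$qvalue) & res$qvalue <= x$fdr
  graphics::plot(log10(base_mean + 0.5), res$log2fc,
                 col = ifelse(sig, "red3", "grey40"), pch = 20, cex = 0.5,
                 xlab = "log10 mean normalized count",
                 ylab = "log2 fold change", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
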