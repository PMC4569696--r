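#' Pipeline configuration
#'
#' Bundles input paths and every stage threshold. Defaults are the analysis
#' thresholds used throughout the package: 10 RpM in more than half the
#' samples for the miRNA cutoff, 1/100,000 of total reads for the mRNA
#' filter, twofold change at adjusted p <= 0.05 for selection tables, and
#' FDR 0.1 for the RISC/concordance analyses.
#'
#' @param paths named list of input paths as written by
#'   [write_synthetic_dataset()] (elements `global_counts`, `global_samples`,
#'   `risc_counts`, `risc_samples`, `dev_counts`, `dev_samples`,
#'   `gene_lengths`, `timecourse_mirna`, `timecourse_mrna`; `gff3`/`fasta`
#'   optional).
#' @param out_dir directory for stage outputs.
#' @param contrast perturbation contrast, `c(reference, alternative)`.
#' @param dev_contrast developmental contrast.
#' @param rpm_threshold,rpm_sample_fraction miRNA cutoff parameters.
#' @param mrna_fraction_threshold mRNA filter share of total reads.
#' @param fc_threshold,q_threshold twofold selection rule.
#' @param risc_fdr FDR for RISC target calls and concordance.
#' @param cluster_max_gap_bp genomic cluster gap.
#' @param seed seed echoed in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, out_dir,
                            contrast = c("control", "mirOE"),
                            dev_contrast = c("P10", "adult"),
                            rpm_threshold = 10, rpm_sample_fraction = 0.5,
                            mrna_fraction_threshold = 1e-5,
                            fc_threshold = 2, q_threshold = 0.05,
                            risc_fdr = 0.1, cluster_max_gap_bp = 10000,
                            seed = 1L) {
  stopifnot(rpm_threshold > 0, mrna_fraction_threshold > 0, fc_threshold > 0,
            q_threshold > 0, risc_fdr > 0, cluster_max_gap_bp > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load and validate counts; filter low-abundance mRNAs; NB
#' differential expression per fraction (perturbation contrast) and for the
#' developmental contrast; RISC direct-target classification; concordance of
#' perturbation-responsive genes with development; time-course miRNA/target
#' correlations; optional seed-family/cluster organization when annotations
#' are provided. All outputs are written as TSV under `config$out_dir`, and
#' a structured report of per-stage counts is returned. The run is
#' deterministic given identical inputs.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- config$paths
  need <- c("global_counts", "global_samples", "risc_counts", "risc_samples",
            "dev_counts", "dev_samples", "timecourse_mirna", "timecourse_mrna")
  miss <- need[!vapply(need, function(k)
    !is.null(paths[[k]]) && file.exists(paths[[k]]), logical(1))]
  if (length(miss))
    stop("missing or nonexistent input(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  report <- list(seed = config$seed,
                 parameters = config[setdiff(names(config), c("paths", "out_dir"))],
                 stages = list())
  log_stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  global <- load_count_table(paths$global_counts, paths$global_samples)
  risc <- load_count_table(paths$risc_counts, paths$risc_samples)
  dev <- load_count_table(paths$dev_counts, paths$dev_samples)
  for (cm in list(global, risc))
    if (!all(config$contrast %in% cm$sample_meta$condition))
      stop("contrast label(s) absent from sample sheet: ",
           paste(setdiff(config$contrast, cm$sample_meta$condition),
                 collapse = ", "), call. = FALSE)
  if (!all(config$dev_contrast %in% dev$sample_meta$condition))
    stop("developmental contrast label(s) absent from sample sheet",
         call. = FALSE)
  log_stage("load", n_genes = nrow(global$counts),
            n_global = ncol(global$counts), n_risc = ncol(risc$counts),
            n_dev = ncol(dev$counts))

  filt_global <- filter_low_mrnas(global, config$mrna_fraction_threshold)
  filt_risc <- filter_low_mrnas(risc, config$mrna_fraction_threshold)
  universe <- intersect(rownames(filt_global$counts$counts),
                        rownames(filt_risc$counts$counts))
  gcm <- count_matrix(filt_global$counts$counts[universe, , drop = FALSE],
                      filt_global$counts$sample_meta)
  rcm <- count_matrix(filt_risc$counts$counts[universe, , drop = FALSE],
                      filt_risc$counts$sample_meta)
  utils::write.table(filt_global$report, out("filter_global.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(filt_risc$report, out("filter_risc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("filter", input = nrow(global$counts), universe = length(universe))

  fit_global <- nbde(gcm, contrast = config$contrast, fdr = config$risc_fdr)
  fit_risc <- nbde(rcm, contrast = config$contrast, fdr = config$risc_fdr)
  dev_universe <- intersect(universe, rownames(dev$counts))
  dcm <- count_matrix(dev$counts[dev_universe, , drop = FALSE], dev$sample_meta)
  fit_dev <- nbde(dcm, contrast = config$dev_contrast, fdr = config$risc_fdr)
  write_results_table(fit_global$results, out("de_global.tsv"))
  write_results_table(fit_risc$results, out("de_risc.tsv"))
  write_results_table(fit_dev$results, out("de_developmental.tsv"))
  log_stage("de", tested_global = sum(fit_global$results$status != "not_tested"),
            tested_risc = sum(fit_risc$results$status != "not_tested"),
            tested_dev = sum(fit_dev$results$status != "not_tested"))

  fc <- data.frame(feature_id = fit_dev$results$gene_id,
                   signed_fc = signed_fold_change(0, fit_dev$results$log2fc),
                   qvalue = fit_dev$results$qvalue,
                   stringsAsFactors = FALSE)
  fc <- fc[!is.na(fc$qvalue), ]
  sel <- select_changed(fc, config$fc_threshold, config$q_threshold)
  utils::write.table(sel$selected, out("dev_selected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("foldchange", selected = nrow(sel$selected),
            n_up = sel$n_up, n_down = sel$n_down)

  targets <- classify_direct_targets(fit_risc$results, fit_global$results,
                                     fdr = config$risc_fdr)
  write_results_table(targets$calls, out("direct_targets.tsv"))
  log_stage("risc", calls = nrow(targets$calls),
            degradation = sum(targets$calls$mode == "degradation"),
            suppression = sum(targets$calls$mode == "translational_suppression"),
            excluded = nrow(targets$excluded))

  responsive <- fit_global$results[
    !is.na(fit_global$results$qvalue) &
      fit_global$results$qvalue <= config$risc_fdr &
      fit_global$results$gene_id %in% fit_dev$results$gene_id, ]
  conc <- concordance_with_development(responsive, fit_dev$results,
                                       fdr = config$risc_fdr)
  write_results_table(conc$records, out("concordance.tsv"))
  utils::write.table(as.data.frame(unclass(conc$summary)),
                     out("concordance_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("concordance", n_responsive = conc$summary$n_responsive,
            opposite_significant = conc$summary$n_opposite_significant)

  mir_tc <- utils::read.delim(paths$timecourse_mirna, stringsAsFactors = FALSE)
  mrna_tc <- utils::read.delim(paths$timecourse_mrna, stringsAsFactors = FALSE)
  pairs <- unique(data.frame(mirna_id = mir_tc$feature_id,
                             stringsAsFactors = FALSE))
  mrna_ids <- unique(mrna_tc$feature_id)
  n_pairs <- min(nrow(pairs), length(mrna_ids))
  cors <- do.call(rbind, lapply(seq_len(n_pairs), function(i)
    correlate_pairs(mir_tc[mir_tc$feature_id == pairs$mirna_id[i], ],
                    mrna_tc[mrna_tc$feature_id == mrna_ids[i], ])))
  utils::write.table(cors, out("timecourse_correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("timecourse", n_pairs = n_pairs,
            median_r = stats::median(cors$r))

  if (!is.null(paths$gff3) && !is.null(paths$fasta) &&
      file.exists(paths$gff3) && file.exists(paths$fasta)) {
    ann <- load_mirna_annotation(paths$gff3, paths$fasta)
    ann <- group_clusters(group_families(ann), config$cluster_max_gap_bp)
    utils::write.table(ann, out("mirna_organization.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("organize", n_mirnas = nrow(ann),
              n_families = length(unique(ann$family_id)),
              n_clusters = length(unique(ann$cluster_id)))
  }

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(st), unlist(st), sep = "=", collapse = "  ")))
  }
  invisible(x)
}
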