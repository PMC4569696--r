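#' Configuration for the synthetic islet dataset generator
#'
#' Defaults emulate the scale and design of the postnatal islet study the
#' package analyses: ~300 detected miRNAs, a filtered mRNA universe of a few
#' thousand genes, 3-4 biological replicates per group, paired global and
#' Ago2-RISC libraries for a control vs miRNA-overexpression contrast, a
#' developmental (adult vs P10) contrast, and a six-timepoint postnatal
#' series.
#'
#' @param n_mrnas number of mRNAs before filtering (default 5000).
#' @param n_mirnas number of miRNAs (default 300).
#' @param n_per_group biological replicates per group (default 4).
#' @param nb_dispersion NB dispersion alpha of `Var = mu + alpha mu^2`
#'   (default 0.05, constant across genes).
#' @param library_meanlog,library_sdlog log-normal library-size parameters
#'   (defaults `log(2e6)` and 0.25; non-trivial size factors by design).
#' @param n_planted_degradation,n_planted_suppression planted direct targets
#'   per mode (defaults 100 each; disjoint sets).
#' @param planted_lfc_range absolute planted log2 fold change, drawn
#'   uniformly (default `c(1, 2)`).
#' @param n_developmental_de developmentally regulated genes (default 600,
#'   half up, half down in adult vs P10).
#' @param dev_opposite_frac fraction of planted direct targets that are also
#'   developmentally regulated opposite to their perturbation response
#'   (default 0.7).
#' @param timepoints ordered postnatal grid (default P10...adult).
#' @param change_timepoint default step location for time-course plants
#'   (default `"P23"`).
#' @param r_true planted replicate-level correlation between a miRNA and its
#'   target trajectory (default -0.9; replicate noise is solved analytically
#'   from it).
#' @param n_timecourse_pairs planted miRNA/target trajectory pairs
#'   (default 50).
#' @param n_tc_replicates replicates per timepoint (default 4).
#' @param n_clustered_mirnas miRNAs placed into multi-member genomic clusters
#'   (default 60).
#' @param seed mandatory RNG seed (integer).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_mrnas = 5000, n_mirnas = 300, n_per_group = 4,
                              nb_dispersion = 0.05,
                              library_meanlog = log(2e6), library_sdlog = 0.25,
                              n_planted_degradation = 100,
                              n_planted_suppression = 100,
                              planted_lfc_range = c(1, 2),
                              n_developmental_de = 600,
                              dev_opposite_frac = 0.7,
                              timepoints = c("P10", "P15", "P20", "P23", "P31", "adult"),
                              change_timepoint = "P23",
                              r_true = -0.9,
                              n_timecourse_pairs = 50,
                              n_tc_replicates = 4,
                              n_clustered_mirnas = 60,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_planted_degradation + n_planted_suppression > n_mrnas)
    stop("more planted targets than mRNAs", call. = FALSE)
  if (n_developmental_de > n_mrnas)
    stop("more developmental genes than mRNAs", call. = FALSE)
  if (!change_timepoint %in% timepoints)
    stop("change timepoint '", change_timepoint, "' not on the grid", call. = FALSE)
  if (length(timepoints) < 3) stop("need >= 3 timepoints", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

set_sim_seed <- function(seed, offset = 0L) {
  suppressWarnings(
    set.seed(as.integer(seed) + offset, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  )
}

#' Generate paired global/RISC count matrices with planted direct targets
#'
#' Baseline relative abundances are log-normal; library sizes are log-normal;
#' counts are NB with `Var = mu + alpha mu^2`. The perturbation contrast is
#' `control` vs `mirOE` (miRNA overexpression). Degradation-mode plants gain
#' `+lfc` in the RISC fraction and `-lfc` in the global fraction;
#' suppression-mode plants gain `+lfc` in RISC and are untouched globally
#' (clean mode separation by construction). Plants are drawn from genes whose
#' baseline relative abundance clears the detection filter
#' (share >= 5e-5 of reads), since targets are classified among detected
#' mRNAs.
#'
#' @param config a [simulation_config()].
#' @return list with `global` and `risc` ([count_matrix()] each, conditions
#'   `control` / `mirOE`) and `truth` (data.frame `feature_id`, `role`,
#'   `mode`, `lfc_risc`, `lfc_global`).
#' @export
generate_paired_fraction_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set_sim_seed(config$seed, 1L)
  n <- config$n_mrnas
  gene_ids <- sprintf("gene%04d", seq_len(n))
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  w <- w / sum(w)                       # baseline relative abundance

  detectable <- which(w >= 5e-5)
  n_deg <- config$n_planted_degradation
  n_sup <- config$n_planted_suppression
  planted <- sample(detectable, n_deg + n_sup)
  deg <- planted[seq_len(n_deg)]
  sup <- planted[n_deg + seq_len(n_sup)]
  lfc <- stats::runif(n_deg + n_sup, config$planted_lfc_range[1L],
                      config$planted_lfc_range[2L])

  lfc_risc <- numeric(n); lfc_global <- numeric(n)
  lfc_risc[deg] <- lfc[seq_len(n_deg)]
  lfc_risc[sup] <- lfc[n_deg + seq_len(n_sup)]
  lfc_global[deg] <- -lfc[seq_len(n_deg)]

  role <- rep("null", n)
  role[deg] <- "direct_degradation"
  role[sup] <- "direct_suppression"
  mode <- rep(NA_character_, n)
  mode[deg] <- "degradation"
  mode[sup] <- "translational_suppression"

  npg <- config$n_per_group
  make_fraction <- function(lfc_vec, fraction) {
    cond <- rep(c("control", "mirOE"), each = npg)
    sample_ids <- sprintf("%s_%s_%d", fraction, cond, rep(seq_len(npg), 2L))
    libs <- stats::rlnorm(2L * npg, config$library_meanlog, config$library_sdlog)
    mu <- matrix(0, n, 2L * npg, dimnames = list(gene_ids, sample_ids))
    for (j in seq_len(2L * npg)) {
      wj <- if (cond[j] == "mirOE") w * 2^lfc_vec else w
      mu[, j] <- wj / sum(wj) * libs[j]
    }
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$nb_dispersion),
                  n, 2L * npg, dimnames = dimnames(mu))
    count_matrix(cnt, data.frame(sample_id = sample_ids, fraction = fraction,
                                 condition = cond, stringsAsFactors = FALSE))
  }
  global <- make_fraction(lfc_global, "global")
  risc <- make_fraction(lfc_risc, "RISC")
  truth <- data.frame(feature_id = gene_ids, role = role, mode = mode,
                      lfc_risc = lfc_risc, lfc_global = lfc_global,
                      stringsAsFactors = FALSE)
  list(global = global, risc = risc, truth = truth)
}

#' Generate a developmental (adult vs P10) global count matrix
#'
#' Reuses the perturbation truth: a configurable fraction of planted direct
#' targets is developmentally regulated in the direction opposite to their
#' global perturbation response (the developmental decline of the miRNA
#' releases its targets), plus `n_developmental_de` independent
#' developmental genes, half up and half down.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [generate_paired_fraction_counts()].
#' @return list with `counts` ([count_matrix()], conditions `P10` / `adult`)
#'   and `truth` (per-gene `feature_id`, `dev_role`, `lfc_dev`).
#' @export
generate_developmental_counts <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set_sim_seed(config$seed, 2L)
  n <- config$n_mrnas
  gene_ids <- truth$feature_id
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  w <- w / sum(w)

  lfc_dev <- numeric(n)
  planted <- which(truth$role != "null")
  flips <- planted[stats::runif(length(planted)) < config$dev_opposite_frac]
  # perturbation = miRNA gain; development = miRNA loss, so targets move up
  lfc_dev[flips] <- abs(truth$lfc_risc[flips])
  free <- setdiff(which(w >= 5e-5), planted)
  ndev <- min(config$n_developmental_de, length(free))
  dev_genes <- sample(free, ndev)
  half <- floor(ndev / 2)
  sgn <- c(rep(1, half), rep(-1, ndev - half))
  lfc_dev[dev_genes] <- sgn * stats::runif(ndev, config$planted_lfc_range[1L],
                                           config$planted_lfc_range[2L])

  dev_role <- rep("null", n)
  dev_role[lfc_dev > 0] <- "developmental_up"
  dev_role[lfc_dev < 0] <- "developmental_down"

  npg <- config$n_per_group
  cond <- rep(c("P10", "adult"), each = npg)
  sample_ids <- sprintf("dev_%s_%d", cond, rep(seq_len(npg), 2L))
  libs <- stats::rlnorm(2L * npg, config$library_meanlog, config$library_sdlog)
  mu <- matrix(0, n, 2L * npg, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(2L * npg)) {
    wj <- if (cond[j] == "adult") w * 2^lfc_dev else w
    mu[, j] <- wj / sum(wj) * libs[j]
  }
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion),
                n, 2L * npg, dimnames = dimnames(mu))
  cm <- count_matrix(cnt, data.frame(sample_id = sample_ids,
                                     fraction = "global", condition = cond,
                                     stringsAsFactors = FALSE))
  list(counts = cm,
       truth = data.frame(feature_id = gene_ids, dev_role = dev_role,
                          lfc_dev = lfc_dev, stringsAsFactors = FALSE))
}

#' Generate anticorrelated miRNA/target postnatal time courses
#'
#' Each planted miRNA follows a unit step trajectory (down for half the
#' pairs, up for the other half) switching at `change_timepoint`; its target
#' follows the mirrored trajectory. Gaussian replicate noise is calibrated so
#' that the replicate-level correlation between a pair equals `r_true`:
#' `sigma^2 = var_pop(trajectory) * (1/|r_true| - 1)`. Averaging replicates
#' within timepoints (the default pairing of [correlate_pairs()]) therefore
#' estimates a correlation stronger than `r_true`. With `r_true = 0` targets
#' are flat noise, independent of their miRNA.
#'
#' @param config a [simulation_config()].
#' @return list with `mirna_tc`, `mrna_tc` (long-format data.frames:
#'   `feature_id`, `timepoint`, `replicate`, `value`) and `truth`
#'   (`mirna_id`, `mrna_id`, `direction`, `change_timepoint`, `r_true`).
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set_sim_seed(config$seed, 3L)
  tps <- config$timepoints
  k <- match(config$change_timepoint, tps)
  npairs <- config$n_timecourse_pairs
  nrep <- config$n_tc_replicates
  step <- as.numeric(seq_along(tps) >= k)      # 0 before change, 1 after
  var_pop <- stats::var(step) * (length(step) - 1) / length(step)
  sigma <- if (config$r_true == 0) sqrt(var_pop)
           else sqrt(var_pop * (1 / abs(config$r_true) - 1))

  rows <- function(id, traj) {
    data.frame(feature_id = id,
               timepoint = rep(tps, each = nrep),
               replicate = rep(seq_len(nrep), length(tps)),
               value = rep(traj, each = nrep) +
                 stats::rnorm(length(tps) * nrep, 0, sigma),
               stringsAsFactors = FALSE)
  }
  mirna_list <- vector("list", npairs)
  mrna_list <- vector("list", npairs)
  direction <- rep(c("down", "up"), length.out = npairs)
  for (i in seq_len(npairs)) {
    mir_traj <- if (direction[i] == "down") 1 - step else step
    tgt_traj <- if (config$r_true == 0) rep(0.5, length(tps)) else 1 - mir_traj
    mirna_list[[i]] <- rows(sprintf("syn-mir-tc-%03d", i), mir_traj)
    mrna_list[[i]] <- rows(sprintf("target-tc-%03d", i), tgt_traj)
  }
  truth <- data.frame(
    mirna_id = sprintf("syn-mir-tc-%03d", seq_len(npairs)),
    mrna_id = sprintf("target-tc-%03d", seq_len(npairs)),
    direction = direction,
    change_timepoint = config$change_timepoint,
    r_true = config$r_true,
    stringsAsFactors = FALSE
  )
  list(mirna_tc = do.call(rbind, mirna_list),
       mrna_tc = do.call(rbind, mrna_list),
       truth = truth)
}

random_rna <- function(n_len) {
  paste(sample(c("A", "C", "G", "U"), n_len, replace = TRUE), collapse = "")
}

#' Generate miRNA annotations with planted cluster and family structure
#'
#' miRNAs are organized into genomic clusters (members within the 10 kb
#' polycistron gap on one chromosome and strand; distinct clusters separated
#' by megabases) and seed families. One family is planted across two
#' different clusters, mirroring the situation where paralogous polycistrons
#' carry miRNAs with a shared seed. Optionally, each planted direct-target
#' mRNA from `truth` receives a synthetic 3'UTR carrying at least one
#' reverse-complement seed site of its assigned miRNA.
#'
#' @param config a [simulation_config()].
#' @param truth optional perturbation truth table; when given, planted
#'   targets are assigned miRNAs and UTRs.
#' @return list with `annotations` (data.frame as in
#'   [load_mirna_annotation()], seeds filled), `family_truth` and
#'   `cluster_truth` (named membership vectors), and `utrs` (data.frame
#'   `mrna_id`, `mirna_id`, `utr`; `NULL` without `truth`).
#' @export
generate_mirna_annotations <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set_sim_seed(config$seed, 4L)
  n <- config$n_mirnas
  ids <- sprintf("syn-mir-%03d", seq_len(n))

  # cluster sizes: n_clustered miRNAs in clusters of 2-5, rest singletons
  n_clustered <- min(config$n_clustered_mirnas, n)
  sizes <- integer(0)
  left <- n_clustered
  while (left >= 2L) {
    s <- sample(2:5, 1L)
    s <- min(s, left)
    if (s < 2L) break
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes <- c(sizes, rep(1L, n - sum(sizes)))
  cluster_of <- rep(seq_along(sizes), sizes)

  chrom <- sample(paste0("chr", 1:20), length(sizes), replace = TRUE)
  strand <- sample(c("+", "-"), length(sizes), replace = TRUE)
  start <- integer(n); end <- integer(n)
  pos <- 0L
  for (cl in seq_along(sizes)) {
    base <- cl * 2000000L            # clusters never within the join gap
    cursor <- base
    for (m in which(cluster_of == cl)) {
      len <- sample(60:90, 1L)
      start[m] <- cursor
      end[m] <- cursor + len - 1L
      cursor <- end[m] + sample(200:5000, 1L)  # intra-cluster gap << 10 kb
    }
  }

  # unique seeds, then plant one family across two multi-member clusters
  seqs <- character(n)
  repeat {
    seqs <- vapply(seq_len(n), function(i) random_rna(22L), character(1))
    if (!anyDuplicated(substr(seqs, 2L, 8L))) break
  }
  multi <- which(sizes >= 2L)
  if (length(multi) >= 2L) {
    cl_pair <- multi[1:2]
    a <- which(cluster_of == cl_pair[1L])[1L]
    b <- which(cluster_of == cl_pair[2L])[1L]
    substr(seqs[b], 2L, 8L) <- substr(seqs[a], 2L, 8L)
  }

  ann <- data.frame(
    mirna_id = ids, chrom = chrom[cluster_of],
    start = start, end = end, strand = strand[cluster_of],
    mature_sequence = seqs,
    seed = substr(seqs, 2L, 8L),
    family_id = NA_character_, cluster_id = NA_character_,
    stringsAsFactors = FALSE
  )
  family_truth <- stats::setNames(
    vapply(split(ids, ann$seed), min, character(1))[ann$seed], ids)
  cluster_truth <- stats::setNames(
    vapply(split(ids, cluster_of), min, character(1))[as.character(cluster_of)], ids)

  utrs <- NULL
  if (!is.null(truth)) {
    targets <- truth$feature_id[truth$role != "null"]
    mir_for <- sample(ids, length(targets), replace = TRUE)
    utrs <- data.frame(
      mrna_id = targets, mirna_id = mir_for,
      utr = vapply(mir_for, function(mid) {
        site <- rna_reverse_complement(ann$seed[ann$mirna_id == mid])
        left <- random_rna(sample(100:300, 1L))
        right <- random_rna(sample(100:300, 1L))
        paste0(left, site, right)
      }, character(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  list(annotations = ann, family_truth = family_truth,
       cluster_truth = cluster_truth, utrs = utrs)
}

#' Write a GFF3 + FASTA pair for synthetic miRNA annotations
#'
#' @param annotations annotation data.frame (1-based inclusive coordinates).
#' @param gff3_path,fasta_path output paths.
#' @return Invisibly, `gff3_path`.
#' @export
write_mirna_annotation <- function(annotations, gff3_path, fasta_path) {
  gff <- c("##gff-version 3",
           sprintf("%s\triscmir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                   annotations$chrom, annotations$start, annotations$end,
                   annotations$strand, annotations$mirna_id))
  writeLines(gff, gff3_path)
  fasta <- as.vector(rbind(paste0(">", annotations$mirna_id),
                           annotations$mature_sequence))
  writeLines(fasta, fasta_path)
  invisible(gff3_path)
}

#' Write the full synthetic fixture tree to a directory
#'
#' Emits count TSVs and sample sheets for the perturbation (global + RISC)
#' and developmental contrasts, miRNA GFF3/FASTA annotations, gene lengths,
#' long-format time courses, and all truth tables. Fully deterministic under
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paired <- generate_paired_fraction_counts(config)
  dev <- generate_developmental_counts(config, paired$truth)
  tc <- generate_timecourse(config)
  ann <- generate_mirna_annotations(config, paired$truth)

  write_count_table(paired$global, p("global_counts.tsv"), p("global_samples.tsv"))
  write_count_table(paired$risc, p("risc_counts.tsv"), p("risc_samples.tsv"))
  write_count_table(dev$counts, p("dev_counts.tsv"), p("dev_samples.tsv"))
  utils::write.table(paired$truth, p("truth_perturbation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dev$truth, p("truth_developmental.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  set_sim_seed(config$seed, 5L)
  lengths <- data.frame(gene_id = paired$truth$feature_id,
                        exonic_length_bp = sample(500:5000, config$n_mrnas,
                                                  replace = TRUE))
  utils::write.table(lengths, p("gene_lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_mirna_annotation(ann$annotations, p("mirnas.gff3"), p("mirnas.fa"))
  utils::write.table(tc$mirna_tc, p("timecourse_mirna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tc$mrna_tc, p("timecourse_mrna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tc$truth, p("truth_timecourse.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ann$utrs))
    utils::write.table(ann$utrs, p("target_utrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(list(
    global_counts = p("global_counts.tsv"), global_samples = p("global_samples.tsv"),
    risc_counts = p("risc_counts.tsv"), risc_samples = p("risc_samples.tsv"),
    dev_counts = p("dev_counts.tsv"), dev_samples = p("dev_samples.tsv"),
    truth_perturbation = p("truth_perturbation.tsv"),
    truth_developmental = p("truth_developmental.tsv"),
    gene_lengths = p("gene_lengths.tsv"),
    gff3 = p("mirnas.gff3"), fasta = p("mirnas.fa"),
    timecourse_mirna = p("timecourse_mirna.tsv"),
    timecourse_mrna = p("timecourse_mrna.tsv"),
    truth_timecourse = p("truth_timecourse.tsv"),
    target_utrs = p("target_utrs.tsv")
  ))
}
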