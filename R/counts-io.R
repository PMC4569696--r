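#' Construct a validated count matrix
#'
#' A `count_matrix` couples an integer genes-by-samples read-count matrix with
#' per-sample metadata (fraction, condition, optional timepoint). All
#' differential-expression statistics in this package operate on raw counts;
#' abundance units (RpM, FPKM) are derived views, never inputs to testing.
#'
#' @param counts integer matrix, genes in rows and samples in columns, with
#'   unique row and column names. Counts must be non-negative whole numbers;
#'   missing values are not permitted.
#' @param sample_meta data.frame with one row per column of `counts`, columns
#'   `sample_id`, `fraction` (one of `"global"`, `"RISC"`), `condition`, and
#'   optionally `timepoint` and `library_total_reads` (defaults to the column
#'   sum).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `sample_meta` (data.frame, rows aligned to columns).
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry gene (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix", call. = FALSE)
  if (anyNA(counts))
    stop("missing counts are not permitted; matrices must be complete", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  sample_meta <- validate_sample_sheet(sample_meta, colnames(counts))
  if (is.null(sample_meta$library_total_reads))
    sample_meta$library_total_reads <- unname(colSums(counts))
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat("fractions: ", paste(unique(x$sample_meta$fraction), collapse = ", "),
      "; conditions: ", paste(unique(x$sample_meta$condition), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

valid_fractions <- c("global", "RISC")

validate_sample_sheet <- function(sheet, sample_ids) {
  need <- c("sample_id", "fraction", "condition")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  absent <- setdiff(sample_ids, sheet$sample_id)
  if (length(absent))
    stop("sample(s) in count table absent from sample sheet: ",
         paste(absent, collapse = ", "), call. = FALSE)
  bad_frac <- setdiff(unique(sheet$fraction), valid_fractions)
  if (length(bad_frac))
    stop("unknown fraction label(s): ", paste(bad_frac, collapse = ", "),
         "; expected one of ", paste(valid_fractions, collapse = ", "), call. = FALSE)
  if (anyNA(sheet$fraction) || anyNA(sheet$condition))
    stop("every sample needs a fraction and a condition", call. = FALSE)
  sheet <- sheet[match(sample_ids, sheet$sample_id), , drop = FALSE]
  if (is.null(sheet$timepoint)) sheet$timepoint <- NA_character_
  rownames(sheet) <- NULL
  sheet
}

#' Read a count table and its sample sheet from TSV
#'
#' The count table is tab-delimited with a header row of sample ids and gene
#' ids in the first column; the sample sheet is tab-delimited with columns
#' `sample_id`, `fraction`, `condition` and optionally `timepoint`,
#' `library_total_reads`. Row and column order of the table are preserved.
#'
#' @param path path to the TSV count table.
#' @param sample_sheet_path path to the TSV sample sheet covering all columns.
#' @return A [count_matrix()].
#' @export
load_count_table <- function(path, sample_sheet_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a gene-id column and >=1 sample", call. = FALSE)
  gene_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count for gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]), call. = FALSE)
  }
  if (any(vals != round(vals) | vals < 0, na.rm = TRUE)) {
    bad <- which(vals != round(vals) | vals < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 gene_ids[bad[1L]], colnames(vals)[bad[2L]]), call. = FALSE)
  }
  rownames(vals) <- gene_ids
  sheet <- utils::read.delim(sample_sheet_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  count_matrix(vals, sheet)
}

#' Write a count matrix (and its sample sheet) to TSV
#'
#' @param cm a [count_matrix()].
#' @param path output TSV path for the counts.
#' @param sample_sheet_path optional output path for the sample sheet.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(cm, path, sample_sheet_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(cm$sample_meta, sample_sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table (exonic length in bp) from TSV
#'
#' @param path TSV with columns `gene_id` and `exonic_length_bp`.
#' @return Named integer vector of exonic lengths (bp).
#' @export
load_gene_lengths <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "exonic_length_bp") %in% names(tab)))
    stop("gene length table needs columns gene_id, exonic_length_bp", call. = FALSE)
  if (any(tab$exonic_length_bp <= 0))
    stop("exonic lengths must be positive", call. = FALSE)
  stats::setNames(as.integer(tab$exonic_length_bp), tab$gene_id)
}

#' Load miRNA annotations from GFF3 loci and a FASTA of mature sequences
#'
#' GFF3 coordinates are 1-based inclusive (the GFF3 standard) and are kept so
#' in the returned table; interval arithmetic downstream (cluster gap
#' computation) converts to 0-based half-open internally. FASTA records are
#' matched to GFF3 records by id, not by order; an id present in only one of
#' the two files is a cross-reference error.
#'
#' @param gff3_path GFF3 file; each record must carry an `ID` attribute.
#' @param fasta_path FASTA of mature miRNA sequences (RNA alphabet), ids
#'   matching the GFF3 `ID`s.
#' @return data.frame with columns `mirna_id`, `chrom`, `start`, `end`,
#'   `strand`, `mature_sequence`, plus `seed`, `family_id`, `cluster_id`
#'   initialised to `NA` (computed by [seed_sequence()], [group_families()],
#'   [group_clusters()]).
#' @export
load_mirna_annotation <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path)
  loci <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (is.null(loci$ID) || anyNA(loci$ID))
    stop("every GFF3 record needs an ID attribute", call. = FALSE)
  seqs <- Biostrings::readBStringSet(fasta_path)
  fasta_ids <- sub("\\s.*$", "", names(seqs))
  only_fasta <- setdiff(fasta_ids, loci$ID)
  only_gff <- setdiff(loci$ID, fasta_ids)
  if (length(only_fasta) || length(only_gff))
    stop("GFF3/FASTA cross-reference mismatch; only in FASTA: [",
         paste(only_fasta, collapse = ", "), "]; only in GFF3: [",
         paste(only_gff, collapse = ", "), "]", call. = FALSE)
  idx <- match(loci$ID, fasta_ids)
  data.frame(
    mirna_id = loci$ID,
    chrom = as.character(loci$seqnames),
    start = loci$start,
    end = loci$end,
    strand = as.character(loci$strand),
    mature_sequence = as.character(seqs)[idx],
    seed = NA_character_,
    family_id = NA_character_,
    cluster_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

result_schemas <- list(
  de_result = c("gene_id", "mean_A", "mean_B", "log2fc", "pvalue", "qvalue", "status"),
  direct_target_call = c("gene_id", "mode", "risc_log2fc", "risc_q",
                         "global_log2fc", "global_q"),
  concordance_record = c("gene_id", "perturbation_direction",
                         "developmental_direction", "developmental_q", "class")
)

match_schema <- function(records) {
  for (nm in names(result_schemas))
    if (identical(sort(names(records)), sort(result_schemas[[nm]]))) return(nm)
  stop("records do not match a known result schema (or mix schemas); columns: ",
       paste(names(records), collapse = ", "), call. = FALSE)
}

#' Write a results table (DE results, direct-target calls, concordance records)
#'
#' Columns follow the fixed schema order; floats are written with full
#' precision so a read-back reproduces values to at least 1e-6 relative.
#'
#' @param records data.frame matching one of the three result schemas.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  schema <- match_schema(records)
  records <- records[, result_schemas[[schema]], drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return data.frame in the schema's column order.
#' @export
read_results_table <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE)
  match_schema(records)
  records
}
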