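#' Seed sequence of a mature miRNA
#'
#' The seed is nucleotides 2-8 (1-based, inclusive; 7 nt) of the mature
#' sequence, the primary determinant of target recognition. miRNAs sharing a
#' seed form a family.
#'
#' @param mature RNA string(s), alphabet A/C/G/U, length >= 8.
#' @param convert_dna convert `T` to `U` before extraction (default `FALSE`;
#'   a `T` in the input otherwise raises an alphabet error).
#' @return 7-nt seed string(s).
#' @export
seed_sequence <- function(mature, convert_dna = FALSE) {
  mature <- toupper(mature)
  if (convert_dna) mature <- chartr("T", "U", mature)
  if (any(nchar(mature) < 8L))
    stop("mature sequence shorter than 8 nt; no seed can be extracted",
         call. = FALSE)
  if (any(grepl("[^ACGU]", mature))) {
    if (any(grepl("T", mature)))
      stop("sequence contains T; looks like DNA (use convert_dna = TRUE)",
           call. = FALSE)
    stop("sequence contains characters outside the RNA alphabet A/C/G/U",
         call. = FALSE)
  }
  substr(mature, 2L, 8L)
}

#' Group miRNAs into seed families
#'
#' Two miRNAs are in the same family if and only if their seeds are
#' identical. The family id is the lexicographically smallest member id, so
#' assignment is deterministic and invariant to input order.
#'
#' @param annotations data.frame as returned by [load_mirna_annotation()];
#'   `seed` is computed from `mature_sequence` when absent.
#' @return `annotations` with `seed` and `family_id` filled in.
#' @export
group_families <- function(annotations) {
  if (anyNA(annotations$seed))
    annotations$seed <- seed_sequence(annotations$mature_sequence)
  fam <- split(annotations$mirna_id, annotations$seed)
  ids <- vapply(fam, function(members) min(members), character(1))
  annotations$family_id <- unname(ids[annotations$seed])
  annotations
}

#' Group miRNAs into genomic clusters
#'
#' Single-linkage chaining of loci on the same chromosome and strand: two
#' loci join when the gap between them is at most `max_gap_bp`. Input loci
#' are 1-based inclusive (GFF3); the gap is measured on the 0-based half-open
#' scale, i.e. `gap = start_later - end_earlier - 1` in 1-based terms.
#' Transitive closure defines the clusters, so a chain A-B-C with pairwise
#' gaps below the cutoff is one cluster even if A and C are far apart.
#' The cluster id is the lexicographically smallest member id.
#'
#' @param annotations data.frame with `mirna_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param max_gap_bp maximum gap joining two loci (default 10000; the
#'   polycistron heuristic, exposed as a parameter rather than a claim).
#' @return `annotations` with `cluster_id` filled in.
#' @export
group_clusters <- function(annotations, max_gap_bp = 10000) {
  ann <- annotations
  ann$cluster_id <- NA_character_
  for (key in unique(paste(ann$chrom, ann$strand))) {
    sel <- which(paste(ann$chrom, ann$strand) == key)
    ord <- sel[order(ann$start[sel], ann$end[sel], ann$mirna_id[sel])]
    if (length(ord) == 1L) {
      ann$cluster_id[ord] <- ann$mirna_id[ord]
      next
    }
    # chain: break where the gap to the running right edge exceeds the cutoff
    breaks <- integer(0)
    right_edge <- ann$end[ord[1L]]
    for (j in 2:length(ord)) {
      gap <- ann$start[ord[j]] - right_edge - 1L
      if (gap > max_gap_bp) breaks <- c(breaks, j)
      right_edge <- max(right_edge, ann$end[ord[j]])
    }
    grp <- cumsum(seq_along(ord) %in% breaks)
    for (g in unique(grp)) {
      members <- ord[grp == g]
      ann$cluster_id[members] <- min(ann$mirna_id[members])
    }
  }
  ann
}

#' Reverse complement of an RNA string
#'
#' @param rna RNA string (A/C/G/U).
#' @return Reverse-complemented RNA string.
#' @export
rna_reverse_complement <- function(rna) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(rna)))
}

#' Scan a UTR for 7mer-m8-style seed-match sites
#'
#' Returns the 0-based start positions of every occurrence (including
#' overlapping ones) of the reverse complement of the 7-nt seed in the UTR.
#' This is deliberately minimal plumbing for synthetic ground truth - a site
#' presence check, not a target predictor (no wobble pairing, no context
#' scoring, no conservation).
#'
#' @param utr RNA string.
#' @param seed 7-nt seed from [seed_sequence()].
#' @return Integer vector of 0-based match positions (possibly empty).
#' @export
scan_seed_matches <- function(utr, seed) {
  if (nchar(seed) != 7L) stop("seed must be 7 nt", call. = FALSE)
  if (grepl("[^ACGU]", toupper(utr)) || grepl("[^ACGU]", toupper(seed)))
    stop("sequences must be RNA (A/C/G/U)", call. = FALSE)
  site <- rna_reverse_complement(seed)
  hits <- Biostrings::matchPattern(site, Biostrings::RNAString(toupper(utr)))
  Biostrings::start(hits) - 1L
}
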