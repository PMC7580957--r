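# RPKM quantification of features from read alignments.
#
# Counting follows bedtools-multicov semantics: a read is counted for a
# feature when the two intervals share at least one nucleotide, regardless
# of strand (a `stranded` switch restricts to same-strand overlap). The
# RPKM denominator is all primary mapped alignments in the library, not only
# reads over annotated features.

#' Count reads overlapping a feature
#'
#' Any-overlap (>= 1 nt) counting on half-open intervals: a read abutting a
#' feature (`read end == feature start`) does not count.
#'
#' @param reads internal alignment table.
#' @param feature single-row feature data.frame.
#' @param stranded if `TRUE`, only reads on the feature's strand count.
#' @return integer count.
#' @export
count_overlapping_reads <- function(reads, feature, stranded = FALSE) {
  counts <- count_reads_per_feature(reads, feature, stranded = stranded)
  counts[[1]]
}

#' Count reads per feature
#'
#' Vectorized form of [count_overlapping_reads()] over a feature table.
#'
#' @inheritParams count_overlapping_reads
#' @param features feature data.frame.
#' @return integer vector, one count per feature row.
#' @export
count_reads_per_feature <- function(reads, features, stranded = FALSE) {
  check_intervals(features, "count_reads_per_feature")
  if (nrow(reads) == 0) return(integer(nrow(features)))
  check_reads(reads, "count_reads_per_feature")
  rgr <- gr_from_intervals(reads)
  fgr <- gr_from_intervals(features)
  GenomicRanges::countOverlaps(fgr, rgr, minoverlap = 1L,
                               ignore.strand = !stranded)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (feature_length / 1000) / (total_mapped / 1e6)`.
#'
#' @param read_count integer vector of per-feature read counts.
#' @param feature_length integer vector of feature lengths in nt (> 0).
#' @param total_mapped total primary mapped alignments in the library (> 0).
#' @return numeric vector of RPKM values.
#' @export
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
compute_rpkm <- function(read_count, feature_length, total_mapped) {
  if (any(total_mapped == 0)) stop("compute_rpkm: empty library (total_mapped = 0)")
  if (any(feature_length <= 0)) stop("compute_rpkm: feature_length must be > 0")
  if (any(read_count < 0)) stop("compute_rpkm: negative read_count")
  read_count / (feature_length / 1000) / (total_mapped / 1e6)
}

#' Flag expressed features by an RPKM threshold
#'
#' The comparison is strict: a feature at exactly the threshold is not
#' called expressed (the conventional cutoff is written "RPKM > 10").
#'
#' @param records data.frame with an `rpkm` column (see
#'   [expression_table()]).
#' @param threshold RPKM cutoff (default 10).
#' @return `records` with a logical `expressed` column set/replaced.
#' @export
classify_expression <- function(records, threshold = 10) {
  if (!"rpkm" %in% names(records)) stop("classify_expression: no rpkm column")
  records$expressed <- records$rpkm > threshold
  records
}

#' Per-feature expression table
#'
#' Counts reads over each feature, computes RPKM, and applies the
#' expression threshold in one pass.
#'
#' @inheritParams count_reads_per_feature
#' @param threshold RPKM cutoff for the `expressed` call.
#' @param total_mapped library size for the RPKM denominator; defaults to
#'   `nrow(reads)` (all primary mapped alignments supplied).
#' @return data.frame with columns `feature_id`, `length`, `count`,
#'   `total_mapped`, `rpkm`, `expressed`.
#' @export
expression_table <- function(reads, features, threshold = 10,
                             total_mapped = NULL, stranded = FALSE) {
  check_features(features, "expression_table")
  if (is.null(total_mapped)) total_mapped <- nrow(reads)
  counts <- count_reads_per_feature(reads, features, stranded = stranded)
  len <- features$end - features$start
  tab <- data.frame(
    feature_id = features$id,
    length = len,
    count = as.integer(counts),
    total_mapped = as.integer(total_mapped),
    rpkm = compute_rpkm(counts, len, total_mapped),
    stringsAsFactors = FALSE
  )
  classify_expression(tab, threshold)
}
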