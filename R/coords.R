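# Internal coordinate currency: data.frames with columns
#   contig (character), start (integer, 0-based inclusive),
#   end (integer, exclusive), strand (one of "+", "-", ".").
# Reads additionally carry query_length and sample_id; features carry id and
# biotype. Conversion to/from the 1-based GRanges world happens only in the
# helpers below and in the file readers.

STRANDS <- c("+", "-", ".")

#' Construct a genomic interval table
#'
#' The universal coordinate record used throughout the package: 0-based,
#' half-open `[start, end)` spans with an explicit strand.
#'
#' @param contig character vector of contig/chromosome names.
#' @param start integer vector, 0-based inclusive start (>= 0).
#' @param end integer vector, exclusive end; must satisfy `end > start`.
#' @param strand character vector over `{+, -, .}` (`.` = unstranded).
#' @return a data.frame with columns `contig`, `start`, `end`, `strand`.
#' @export
#' @examples
#' genomic_interval("chr1", 100, 130, "+")
genomic_interval <- function(contig, start, end, strand = ".") {
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  check_intervals(df, "genomic_interval")
  df
}

# Validate the interval invariants; `where` names the caller for error messages.
check_intervals <- function(df, where = "interval") {
  stopifnot(is.data.frame(df))
  needed <- c("contig", "start", "end", "strand")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(where, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop(where, ": NA coordinates")
  }
  if (any(df$start < 0)) stop(where, ": negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    stop(where, ": start >= end at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(df$strand %in% STRANDS)) {
    stop(where, ": strand must be one of +, -, .")
  }
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (1-based closed). "." maps to "*".
gr_from_intervals <- function(df) {
  strand <- ifelse(df$strand == ".", "*", df$strand)
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# GRanges -> 0-based half-open data.frame. "*" maps to ".".
intervals_from_gr <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand == "*", ".", strand),
    stringsAsFactors = FALSE
  )
}

# Validate a read-alignment table (interval columns + query_length, sample_id).
check_reads <- function(reads, where = "reads") {
  check_intervals(reads, where)
  if (!"query_length" %in% names(reads)) {
    stop(where, ": missing query_length column")
  }
  if (nrow(reads) > 0 && any(reads$query_length <= 0)) {
    stop(where, ": non-positive query_length")
  }
  invisible(reads)
}

# Validate a feature table (interval columns + id, biotype). Duplicate ids are
# an error because downstream tables key on them.
check_features <- function(features, where = "features") {
  check_intervals(features, where)
  if (!"id" %in% names(features)) stop(where, ": missing id column")
  dup <- unique(features$id[duplicated(features$id)])
  if (length(dup) > 0) {
    stop(where, ": duplicate feature id(s): ", paste(dup, collapse = ", "))
  }
  invisible(features)
}
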