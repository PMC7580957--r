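#' Read strand-resolved read alignments from BED6, SAM, or BAM
#'
#' Produces the package's internal alignment table: one row per primary
#' mapped alignment, coordinates 0-based half-open. SAM/BAM records flagged
#' unmapped, secondary, or supplementary are excluded. For gapped alignments
#' the interval is the reference span (leftmost to rightmost aligned base)
#' and `query_length` is the aligned query length after soft clipping;
#' bacterial Ribo-Seq alignments are effectively ungapped, so the two
#' coincide in practice. Duplicate alignments are kept: no deduplication is
#' applied anywhere in the pipeline.
#'
#' @param path path to a BED6, SAM, or BAM file.
#' @param format one of `"auto"` (by extension), `"bed"`, `"sam"`, `"bam"`.
#' @param sample_id library label stored with every read; defaults to the
#'   file name without extension.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `query_length`, `sample_id` (and `name` for BED input).
#' @export
read_alignments <- function(path, format = c("auto", "bed", "sam", "bam"),
                            sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed", sam = "sam", bam = "bam",
      stop("cannot infer alignment format from extension '.", ext,
           "'; pass format=")
    )
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  reads <- switch(format,
    bed = read_alignments_bed(path),
    sam = read_alignments_bam(sam_to_bam(path)),
    bam = read_alignments_bam(path)
  )
  if (nrow(reads) > 0) reads$sample_id <- sample_id else reads$sample_id <- character(0)
  check_reads(reads, "read_alignments")
  reads
}

# BED6 reader. A light line-level validation pass first, so malformed records
# are reported with their line number; rtracklayer then does the parsing.
read_alignments_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 6) {
      stop("BED line ", i, ": expected 6 fields (strand required), got ",
           length(f))
    }
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      stop("BED line ", i, ": non-integer coordinates")
    }
    if (!f[6] %in% c("+", "-")) {
      stop("BED line ", i, ": missing or invalid strand '", f[6], "'")
    }
  }
  gr <- rtracklayer::import(path, format = "bed")
  df <- intervals_from_gr(gr)
  df$query_length <- df$end - df$start
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  df$name <- nm
  df
}

sam_to_bam <- function(path) {
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
}

read_alignments_bam <- function(path) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag)
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  df <- intervals_from_gr(GenomicRanges::granges(gal))
  df$query_length <- GenomicAlignments::cigarWidthAlongQuerySpace(
    GenomicAlignments::cigar(gal), after.soft.clipping = TRUE
  )
  df
}

#' Write alignments as BED6
#'
#' Inverse of [read_alignments()] for the BED6 dialect: 0-based half-open
#' coordinates, score column fixed at 0.
#'
#' @param reads internal alignment table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(reads, path) {
  check_reads(reads, "write_alignments_bed")
  name <- if ("name" %in% names(reads) && !anyNA(reads$name)) reads$name
          else sprintf("read%d", seq_len(nrow(reads)))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   reads$contig, reads$start, reads$end, name, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits a minimal valid SAM file (header with `@SQ` lines, one ungapped
#' record per read, sequence and quality omitted as `*`). Reverse-strand
#' reads get FLAG 16.
#'
#' @param reads internal alignment table.
#' @param contig_lengths named integer vector of contig lengths for the
#'   header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(reads, contig_lengths, path) {
  check_reads(reads, "write_alignments_sam")
  if (any(!reads$contig %in% names(contig_lengths))) {
    stop("write_alignments_sam: contig absent from contig_lengths")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  name <- if ("name" %in% names(reads) && !anyNA(reads$name)) reads$name
          else sprintf("read%d", seq_len(nrow(reads)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                 name, flag, reads$contig, reads$start + 1L,
                 reads$end - reads$start)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
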