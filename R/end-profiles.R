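# Strand-aware 5'/3' read-end fragmentation profiles.
#
# The 5' end of a read on the + strand is its leftmost aligned base; on the
# - strand its rightmost. Ends are reported in feature-relative coordinates
# oriented 5'->3' along the feature's strand, so profiles of - strand
# features read left-to-right like their transcripts.

#' Remove reads whose fragments were longer than the read length
#'
#' A read exactly at machine read length cannot certify where its fragment
#' ended: its 3' end is a sequencer artifact, not a nuclease cut. Such
#' reads (`query_length >= max_read_len`, boundary inclusive) are removed
#' before end profiling.
#'
#' @param reads internal alignment table.
#' @param max_read_len the sequencing read length of the library, in nt.
#'   There is no default: it must be supplied per library.
#' @return list with elements `kept` and `removed`, an exhaustive disjoint
#'   partition of `reads`.
#' @export
filter_fragment_truncated <- function(reads, max_read_len) {
  if (length(max_read_len) != 1 || is.na(max_read_len) || max_read_len <= 0) {
    stop("filter_fragment_truncated: max_read_len must be a positive integer")
  }
  check_reads(reads, "filter_fragment_truncated")
  keep <- reads$query_length < max_read_len
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Per-feature 5'/3' read-end profile
#'
#' Tallies, for every position of a feature, how many contributing reads
#' have their 5' end and their 3' end there, plus per-position coverage.
#' By default only reads fully contained in the feature contribute
#' (boundary-straddling reads would attribute end positions belonging to
#' neighboring loci); `partial = TRUE` relaxes this to any-overlap, with
#' end events falling outside the feature dropped. Unstranded (`.`) reads
#' never contribute, since end assignment requires orientation.
#'
#' @param reads internal alignment table (strand-resolved).
#' @param feature single-row feature data.frame; must be on `+` or `-`.
#' @param partial allow partially overlapping reads (default `FALSE`).
#' @return object of class `end_profile`: list with `feature_id`, `length`,
#'   `five_prime`, `three_prime`, `depth` (integer vectors indexed by
#'   feature-relative position, element `i` = 0-based position `i - 1`),
#'   `n_reads_used`, `n_reads_filtered` (reads excluded by contig,
#'   containment, or missing strand).
#' @export
compute_end_profile <- function(reads, feature, partial = FALSE) {
  if (nrow(feature) != 1) stop("compute_end_profile: feature must be a single row")
  check_features(feature, "compute_end_profile")
  if (!feature$strand %in% c("+", "-")) {
    stop("end profiling requires oriented feature (strand + or -), got '",
         feature$strand, "' for ", feature$id)
  }
  check_reads(reads, "compute_end_profile")
  L <- feature$end - feature$start
  oriented <- reads$strand %in% c("+", "-") & reads$contig == feature$contig
  if (partial) {
    use <- oriented & reads$start < feature$end & reads$end > feature$start
  } else {
    use <- oriented & reads$start >= feature$start & reads$end <= feature$end
  }
  r <- reads[use, , drop = FALSE]

  five_g <- ifelse(r$strand == "+", r$start, r$end - 1L)
  three_g <- ifelse(r$strand == "+", r$end - 1L, r$start)
  to_rel <- function(g) {
    if (feature$strand == "+") g - feature$start else feature$end - 1L - g
  }
  five_rel <- to_rel(five_g)
  three_rel <- to_rel(three_g)

  in_span <- function(x) x >= 0 & x < L
  five_prime <- tabulate(five_rel[in_span(five_rel)] + 1L, nbins = L)
  three_prime <- tabulate(three_rel[in_span(three_rel)] + 1L, nbins = L)

  # coverage by difference array, clipped to the feature span
  depth <- integer(L)
  if (nrow(r) > 0) {
    rel_s <- to_rel(if (feature$strand == "+") r$start else r$end - 1L)
    rel_e <- rel_s + (r$end - r$start)
    rel_s <- pmax(rel_s, 0L)
    rel_e <- pmin(rel_e, L)
    d <- integer(L + 1L)
    inc <- tabulate(rel_s + 1L, nbins = L + 1L)
    dec <- tabulate(rel_e + 1L, nbins = L + 1L)
    depth <- cumsum(inc - dec)[seq_len(L)]
  }

  structure(
    list(feature_id = feature$id, length = L,
         five_prime = as.integer(five_prime),
         three_prime = as.integer(three_prime),
         depth = as.integer(depth),
         n_reads_used = nrow(r),
         n_reads_filtered = nrow(reads) - nrow(r)),
    class = "end_profile"
  )
}

#' @export
print.end_profile <- function(x, ...) {
  cat("end_profile '", x$feature_id, "': ", x$length, " nt, ",
      x$n_reads_used, " reads used (", x$n_reads_filtered, " excluded), ",
      sum(x$five_prime), " 5' ends, ", sum(x$three_prime), " 3' ends\n",
      sep = "")
  invisible(x)
}

#' Convert an end profile to a data.frame
#'
#' @param x an `end_profile`.
#' @param ... unused.
#' @return data.frame with columns `position` (0-based feature-relative),
#'   `five_prime`, `three_prime`, `depth`.
#' @export
as.data.frame.end_profile <- function(x, ...) {
  data.frame(position = seq_len(x$length) - 1L,
             five_prime = x$five_prime,
             three_prime = x$three_prime,
             depth = x$depth)
}

#' Write an end profile as genomic bedGraph tracks
#'
#' Emits three tracks (5' ends, 3' ends, depth) in genomic coordinates; for
#' a `-` strand feature the feature-relative arrays are reversed back onto
#' the forward genomic axis, so reading the tracks and re-mapping restores
#' the profile exactly.
#'
#' @param profile an `end_profile`.
#' @param feature the single-row feature it was computed over.
#' @param prefix output path prefix; files are
#'   `<prefix>_5p.bedGraph`, `<prefix>_3p.bedGraph`, `<prefix>_depth.bedGraph`.
#' @return named character vector of the three paths, invisibly.
#' @export
profile_to_tracks <- function(profile, feature, prefix) {
  stopifnot(inherits(profile, "end_profile"))
  if (profile$length != feature$end - feature$start) {
    stop("profile_to_tracks: profile length does not match feature span")
  }
  orient <- function(v) if (feature$strand == "+") v else rev(v)
  paths <- c(five_prime = paste0(prefix, "_5p.bedGraph"),
             three_prime = paste0(prefix, "_3p.bedGraph"),
             depth = paste0(prefix, "_depth.bedGraph"))
  write_bedgraph(orient(profile$five_prime), feature, paths["five_prime"])
  write_bedgraph(orient(profile$three_prime), feature, paths["three_prime"])
  write_bedgraph(orient(profile$depth), feature, paths["depth"])
  invisible(paths)
}
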