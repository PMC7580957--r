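# bedGraph tracks: the package's standard-format surrogate for genome-browser
# coverage views. Written run-length merged; read back via rtracklayer.

#' Write a per-position value vector as bedGraph
#'
#' `values[i]` is the value at genomic position `interval$start + i - 1`
#' (0-based). Runs of equal adjacent values are merged into single bedGraph
#' lines, so write-then-read reproduces the vector exactly.
#'
#' @param values numeric vector, one value per position of `interval`.
#' @param interval single-row interval data.frame (see [genomic_interval()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, interval, path) {
  check_intervals(interval, "write_bedgraph")
  if (nrow(interval) != 1) stop("write_bedgraph: interval must be a single row")
  len <- interval$end - interval$start
  if (length(values) != len) {
    stop("write_bedgraph: length(values) = ", length(values),
         " but interval spans ", len, " positions")
  }
  r <- rle(as.numeric(values))
  ends <- interval$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  val <- ifelse(r$values == round(r$values),
                format(r$values, scientific = FALSE, trim = TRUE),
                format(r$values, scientific = FALSE, trim = TRUE, digits = 15))
  writeLines(sprintf("%s\t%d\t%d\t%s", interval$contig, starts, ends, val),
             path)
  invisible(path)
}

#' Read a bedGraph track back as a per-position vector
#'
#' Inverse of [write_bedgraph()] over a known interval: positions of the
#' interval not covered by any bedGraph line are 0.
#'
#' @param path bedGraph file.
#' @param interval single-row interval data.frame giving the span to
#'   materialize.
#' @return numeric vector of length `interval$end - interval$start`.
#' @export
read_bedgraph <- function(path, interval) {
  check_intervals(interval, "read_bedgraph")
  if (nrow(interval) != 1) stop("read_bedgraph: interval must be a single row")
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- intervals_from_gr(gr)
  df$score <- gr$score
  len <- interval$end - interval$start
  values <- numeric(len)
  df <- df[df$contig == interval$contig &
             df$end > interval$start & df$start < interval$end, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    s <- max(df$start[i], interval$start) - interval$start
    e <- min(df$end[i], interval$end) - interval$start
    values[(s + 1):e] <- df$score[i]
  }
  values
}
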