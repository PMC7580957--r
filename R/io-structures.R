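# Vienna-style dot-bracket structure records. No installed R package parses
# this three-line format, so the reader/writer here is hand-written.

#' Construct a structure annotation
#'
#' Couples a sequence with its dot-bracket secondary structure and derives
#' the per-position paired mask. Validates that the two strings have equal
#' length, that parentheses balance, and that only `(`, `)`, `.` occur.
#'
#' @param feature_id identifier for the structured feature.
#' @param sequence nucleotide string over `A,C,G,T,U,N`.
#' @param dotbracket structure string over `(`, `)`, `.`.
#' @return object of class `structure_annotation`: a list with
#'   `feature_id`, `sequence`, `dotbracket`, `paired_mask` (logical,
#'   `TRUE` where the base is in a stem), `length`.
#' @export
#' @examples
#' s <- structure_annotation("x", "GGGGAAAACCCC", "((((....))))")
#' s$paired_mask
structure_annotation <- function(feature_id, sequence, dotbracket) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(dotbracket)) {
    stop("structure_annotation '", feature_id,
         "': sequence and structure lengths differ (",
         nchar(sequence), " vs ", nchar(dotbracket), ")")
  }
  sc <- strsplit(dotbracket, "")[[1]]
  if (!all(sc %in% c("(", ")", "."))) {
    stop("structure_annotation '", feature_id,
         "': structure may contain only '(', ')', '.'")
  }
  depth <- cumsum((sc == "(") - (sc == ")"))
  if (any(depth < 0) || (length(depth) > 0 && depth[length(depth)] != 0)) {
    stop("structure_annotation '", feature_id, "': unbalanced parentheses")
  }
  if (grepl("[^ACGTUN]", sequence)) {
    stop("structure_annotation '", feature_id,
         "': sequence contains non-nucleotide characters")
  }
  structure(
    list(feature_id = feature_id, sequence = sequence,
         dotbracket = dotbracket, paired_mask = sc != ".",
         length = nchar(sequence)),
    class = "structure_annotation"
  )
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat("structure_annotation '", x$feature_id, "': ", x$length, " nt, ",
      sum(x$paired_mask), " paired positions\n", sep = "")
  invisible(x)
}

#' Read dot-bracket structure records
#'
#' Expects Vienna-style triples: a `>header` line, the sequence, then the
#' dot-bracket string. Every record is validated (balance, equal lengths)
#' and its paired mask computed.
#'
#' @param path text file of dot-bracket records.
#' @return list of [structure_annotation()] objects, named by feature id.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) stop("dot-bracket file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0 && length(lines) > 0) {
    stop("dot-bracket file has no '>' headers: ", path)
  }
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    i <- hdr[k]
    if (i + 2 > length(lines) || (k < length(hdr) && hdr[k + 1] < i + 3)) {
      stop("dot-bracket record '", lines[i], "' is not a (header, sequence, ",
           "structure) triple")
    }
    id <- sub("^>\\s*", "", lines[i])
    id <- strsplit(id, "[ \t]")[[1]][1]
    out[[k]] <- structure_annotation(id, lines[i + 1], lines[i + 2])
  }
  names(out) <- vapply(out, function(s) s$feature_id, character(1))
  out
}

#' Write dot-bracket structure records
#'
#' @param structures list of [structure_annotation()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structures, path) {
  if (inherits(structures, "structure_annotation")) structures <- list(structures)
  lines <- unlist(lapply(structures, function(s) {
    c(paste0(">", s$feature_id), s$sequence, s$dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}
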