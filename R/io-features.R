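# GFF3 feature I/O and the Prodigal `-s` start-score table.

# GFF `type` column -> internal biotype vocabulary.
BIOTYPES <- c("ncRNA", "CDS", "ORF_candidate", "CRISPR_repeat",
              "CRISPR_spacer", "other")

gff_type_to_biotype <- function(type) {
  out <- rep("other", length(type))
  out[type == "ncRNA"] <- "ncRNA"
  out[type == "CDS"] <- "CDS"
  out[type %in% c("ORF", "ORF_candidate")] <- "ORF_candidate"
  out[type %in% c("repeat_region", "direct_repeat", "repeat_unit")] <- "CRISPR_repeat"
  out
}

biotype_to_gff_type <- function(biotype) {
  switch_map <- c(ncRNA = "ncRNA", CDS = "CDS", ORF_candidate = "ORF_candidate",
                  CRISPR_repeat = "repeat_region", CRISPR_spacer = "CRISPR_spacer",
                  other = "region")
  unname(switch_map[biotype])
}

#' Read features from a GFF3 file
#'
#' GFF3 coordinates (1-based, inclusive) are converted to the internal
#' 0-based half-open convention at this boundary. The GFF `ID` attribute
#' becomes the feature id and must be unique; the GFF `type` column is
#' mapped onto the internal biotype vocabulary (`ncRNA`, `CDS`,
#' `ORF_candidate`, `CRISPR_repeat`, `CRISPR_spacer`, `other`).
#'
#' @param path GFF3 file.
#' @param biotype_filter optional character vector; only features whose
#'   biotype is in this set are returned.
#' @return feature data.frame with columns `id`, `contig`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
read_gff_features <- function(path, biotype_filter = NULL) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- intervals_from_gr(gr)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  if (anyNA(id)) {
    id[is.na(id)] <- sprintf("feature_%d", which(is.na(id)))
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    stop("read_gff_features: duplicate ID attribute(s): ",
         paste(dup, collapse = ", "))
  }
  type <- as.character(gr$type)
  features <- data.frame(
    id = id, contig = df$contig, start = df$start, end = df$end,
    strand = df$strand, biotype = gff_type_to_biotype(type),
    stringsAsFactors = FALSE
  )
  check_features(features, "read_gff_features")
  if (!is.null(biotype_filter)) {
    features <- features[features$biotype %in% biotype_filter, , drop = FALSE]
    rownames(features) <- NULL
  }
  features
}

#' Write features as GFF3
#'
#' Inverse of [read_gff_features()]: internal 0-based half-open coordinates
#' go back to 1-based inclusive GFF3, biotypes back to GFF `type` values.
#'
#' @param features feature data.frame.
#' @param path output path.
#' @param source value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff_features <- function(features, path, source = "ribofrag") {
  check_features(features, "write_gff_features")
  strand <- ifelse(features$strand == ".", ".", features$strand)
  type <- vapply(features$biotype, biotype_to_gff_type, character(1))
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$contig, source, type,
                     features$start + 1L, features$end,
                     strand, features$id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Prodigal `-s` start-score table
#'
#' Parses the intermediate output Prodigal writes under `-s`: per-sequence
#' `# Sequence Data:` comment lines carrying the contig name, a column
#' header row, and one tab-delimited row per candidate ORF with 1-based
#' inclusive `Beg`/`End` coordinates, strand, total/coding/start scores and
#' the RBS motif call. Coordinates are converted to 0-based half-open.
#'
#' @param path Prodigal `-s` output file.
#' @return data.frame with columns `orf_id`, `contig`, `start`, `end`,
#'   `strand`, `start_score`, `coding_score`, `rbs_motif` (empty string when
#'   Prodigal reports `None`).
#' @export
read_prodigal_scores <- function(path) {
  if (!file.exists(path)) stop("Prodigal score file not found: ", path)
  lines <- readLines(path)
  contig <- NA_character_
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec('seqhdr="([^"]*)"', ln))[[1]]
      if (length(m) == 2) contig <- strsplit(m[2], "[ \t]")[[1]][1]
      next
    }
    f <- strsplit(ln, "\t")[[1]]
    if (f[1] == "Beg") next  # column header row
    if (length(f) < 8) stop("prodigal scores line ", i, ": expected >= 8 fields")
    beg <- suppressWarnings(as.integer(f[1]))
    end <- suppressWarnings(as.integer(f[2]))
    codpot <- suppressWarnings(as.numeric(f[5]))
    strtsc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(beg) || is.na(end)) {
      stop("prodigal scores line ", i, ": non-numeric coordinate")
    }
    if (is.na(codpot) || is.na(strtsc)) {
      stop("prodigal scores line ", i, ": non-numeric score field")
    }
    if (!f[3] %in% c("+", "-")) {
      stop("prodigal scores line ", i, ": invalid strand '", f[3], "'")
    }
    if (is.na(contig)) {
      stop("prodigal scores line ", i, ": data row before any Sequence Data header")
    }
    rows[[i]] <- data.frame(
      contig = contig, start = beg - 1L, end = end,
      strand = f[3], start_score = strtsc, coding_score = codpot,
      rbs_motif = if (f[8] %in% c("None", "")) "" else f[8],
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(orf_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), start_score = numeric(0),
                      coding_score = numeric(0), rbs_motif = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$orf_id <- sprintf("orf_%s_%d_%d_%s", out$contig, out$start, out$end,
                        out$strand)
  rownames(out) <- NULL
  check_intervals(out, "read_prodigal_scores")
  out[, c("orf_id", "contig", "start", "end", "strand", "start_score",
          "coding_score", "rbs_motif")]
}
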