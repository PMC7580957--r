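# Exhaustive ORF enumeration, Shine-Dalgarno detection, and ncRNA/ORF
# overlap classification.
#
# Conventions follow the bacterial gene-calling defaults: start codons
# {ATG, GTG, TTG}, stops {TAA, TAG, TGA}, the stop codon counted inside the
# ORF length, so a 15 nt minimum means >= 4 aa plus stop. Nested starts
# sharing a stop are reported as distinct candidates.

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Scan one strand of one contig (sequence given 5'->3'). Returns 0-based
# [start, end) spans in the supplied sequence's own coordinates, plus frame
# and start codon. ORFs containing N are skipped and counted.
scan_orfs_one_strand <- function(seq_chr, min_len) {
  L <- nchar(seq_chr)
  has_n <- cumsum(strsplit(seq_chr, "")[[1]] == "N")
  rows <- list()
  n_skipped <- 0L
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3
    if (n_codons < 1) next
    cstart <- frame + 3L * (seq_len(n_codons) - 1L)  # 0-based codon starts
    codons <- substring(seq_chr, cstart + 1L, cstart + 3L)
    start_i <- which(codons %in% START_CODONS)
    stop_i <- which(codons %in% STOP_CODONS)
    if (length(start_i) == 0 || length(stop_i) == 0) next
    # nearest in-frame stop strictly after each start
    nxt <- findInterval(start_i, stop_i) + 1L
    ok <- nxt <= length(stop_i)
    start_i <- start_i[ok]
    nxt <- nxt[ok]
    if (length(start_i) == 0) next
    s0 <- cstart[start_i]
    e0 <- cstart[stop_i[nxt]] + 3L
    len <- e0 - s0
    keep <- len >= min_len
    s0 <- s0[keep]; e0 <- e0[keep]; len <- len[keep]
    start_i <- start_i[keep]
    if (length(s0) == 0) next
    # skip ORFs containing N
    n_inside <- has_n[e0] - ifelse(s0 == 0, 0, has_n[s0])
    n_skipped <- n_skipped + sum(n_inside > 0)
    ok <- n_inside == 0
    if (!any(ok)) next
    rows[[length(rows) + 1]] <- data.frame(
      start = s0[ok], end = e0[ok], frame = frame,
      start_codon = codons[start_i[ok]], length_nt = len[ok],
      stringsAsFactors = FALSE
    )
  }
  list(orfs = if (length(rows)) do.call(rbind, rows) else
         data.frame(start = integer(0), end = integer(0), frame = integer(0),
                    start_codon = character(0), length_nt = integer(0)),
       n_skipped = n_skipped)
}

#' Enumerate all possible ORFs in a genome
#'
#' Scans both strands and all three frames per strand for spans running
#' from a start codon (`ATG`, `GTG`, `TTG`) to the nearest in-frame stop
#' (`TAA`, `TAG`, `TGA`), stop included in the length. Every start sharing
#' a stop yields its own candidate. ORFs containing `N` are skipped (their
#' number is available as `attr(x, "n_skipped_N")`).
#'
#' @param genome a named character vector, `Biostrings::DNAStringSet`, or
#'   path to a FASTA file; DNA over `A,C,G,T,N`.
#' @param min_len minimum ORF length in nt, stop codon included
#'   (default 15, i.e. >= 4 aa).
#' @return data.frame with columns `id`, `contig`, `start`, `end`, `strand`
#'   (0-based half-open genomic coordinates), `frame` (0-2 on the ORF's own
#'   strand), `start_codon`, `length_nt`, `length_aa`
#'   (`length_nt / 3 - 1`, stop excluded).
#' @export
enumerate_orfs <- function(genome, min_len = 15) {
  genome <- as_genome(genome)
  if (min_len < 3) stop("enumerate_orfs: min_len must be >= 3")
  out <- list()
  n_skipped <- 0L
  for (contig in names(genome)) {
    fwd <- as.character(genome[[contig]])
    if (grepl("[^ACGTN]", fwd)) {
      stop("enumerate_orfs: contig '", contig,
           "' contains non-nucleotide characters other than N")
    }
    L <- nchar(fwd)
    sp <- scan_orfs_one_strand(fwd, min_len)
    n_skipped <- n_skipped + sp$n_skipped
    plus <- sp$orfs
    if (nrow(plus) > 0) {
      plus$contig <- contig; plus$strand <- "+"
      out[[length(out) + 1]] <- plus
    }
    rev <- as.character(Biostrings::reverseComplement(genome[[contig]]))
    sm <- scan_orfs_one_strand(rev, min_len)
    n_skipped <- n_skipped + sm$n_skipped
    minus <- sm$orfs
    if (nrow(minus) > 0) {
      # reflect reverse-complement coordinates back onto the forward strand
      s <- L - minus$end
      e <- L - minus$start
      minus$start <- s; minus$end <- e
      minus$contig <- contig; minus$strand <- "-"
      out[[length(out) + 1]] <- minus
    }
  }
  orfs <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), frame = integer(0),
               start_codon = character(0), length_nt = integer(0),
               contig = character(0), strand = character(0),
               stringsAsFactors = FALSE)
  orfs$length_aa <- orfs$length_nt / 3 - 1
  orfs$id <- sprintf("orf_%s_%d_%d_%s", orfs$contig, orfs$start, orfs$end,
                     orfs$strand)
  orfs <- orfs[order(orfs$contig, orfs$start, orfs$end, orfs$strand), ,
               drop = FALSE]
  rownames(orfs) <- NULL
  orfs <- orfs[, c("id", "contig", "start", "end", "strand", "frame",
                   "start_codon", "length_nt", "length_aa")]
  attr(orfs, "n_skipped_N") <- n_skipped
  orfs
}

# Accept DNAStringSet, named character vector, or FASTA path.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- sprintf("contig%d", seq_along(genome))
    }
    bad <- grepl("[^ACGTN]", toupper(genome))
    if (any(bad)) {
      stop("genome contig '", names(genome)[bad][1],
           "' contains non-nucleotide characters other than N")
    }
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet, named character vector, or FASTA path")
}

#' Detect a ribosome-binding site upstream of ORFs
#'
#' Scans the strand-aware upstream window of each ORF start codon for a
#' Shine-Dalgarno-like motif: `TRUE` if some placement of `motif` ending
#' between `spacer_range[1]` and `spacer_range[2]` nt before the start
#' codon matches with at most `max_mismatch` mismatches. ORFs too close to
#' the contig edge for the full window return `FALSE`.
#'
#' @param genome genome as in [enumerate_orfs()].
#' @param orfs ORF table from [enumerate_orfs()] (or any interval table
#'   with `contig`, `start`, `end`, `strand`).
#' @param motif consensus to search for (default `AGGAGG`).
#' @param max_mismatch maximum mismatches tolerated (default 1).
#' @param spacer_range integer length-2 vector: allowed gap in nt between
#'   motif end and start codon (default `c(5, 13)`).
#' @return logical vector, one element per ORF row.
#' @export
find_rbs <- function(genome, orfs, motif = "AGGAGG", max_mismatch = 1,
                     spacer_range = c(5, 13)) {
  genome <- as_genome(genome)
  motif <- toupper(motif)
  mlen <- nchar(motif)
  mchars <- strsplit(motif, "")[[1]]
  if (spacer_range[1] > spacer_range[2] || spacer_range[1] < 0) {
    stop("find_rbs: invalid spacer_range")
  }
  fwd_cache <- list()
  rev_cache <- list()
  res <- logical(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    contig <- orfs$contig[i]
    if (is.null(fwd_cache[[contig]])) {
      fwd_cache[[contig]] <- as.character(genome[[contig]])
      rev_cache[[contig]] <- as.character(
        Biostrings::reverseComplement(genome[[contig]]))
    }
    L <- nchar(fwd_cache[[contig]])
    if (orfs$strand[i] == "+") {
      seq_chr <- fwd_cache[[contig]]
      s0 <- orfs$start[i]               # 0-based start-codon position
    } else {
      seq_chr <- rev_cache[[contig]]
      s0 <- L - orfs$end[i]
    }
    hit <- FALSE
    for (d in spacer_range[1]:spacer_range[2]) {
      ws <- s0 - d - mlen               # 0-based window start
      if (ws < 0) next
      win <- substring(seq_chr, ws + 1L, ws + mlen)
      mm <- sum(strsplit(win, "")[[1]] != mchars)
      if (mm <= max_mismatch) { hit <- TRUE; break }
    }
    res[i] <- hit
  }
  res
}

#' Classify ncRNA overlap with possible ORFs
#'
#' For each ncRNA, finds every enumerated ORF overlapping it by >= 1 nt on
#' either strand and assigns one of three categories:
#' `no_possible_orf` (no overlapping ORF at all), `orf_with_support` (some
#' overlapping ORF has a positive Prodigal start-site score, positive coding
#' score, a detected RBS, or is small, < 50 aa), else `possible_orf_only`.
#' The `supporting` column lists every criterion met by any overlapping ORF.
#'
#' @param ncrnas feature data.frame of ncRNAs.
#' @param orfs ORF table from [enumerate_orfs()]; an optional logical
#'   `has_rbs` column (from [find_rbs()]) feeds the RBS criterion.
#' @param scores optional Prodigal score table from
#'   [read_prodigal_scores()], joined to ORFs by exact coordinates; score
#'   rows whose coordinates match no enumerated ORF are an error.
#' @param small_orf_aa "small ORF" cutoff in amino acids (default 50,
#'   exclusive).
#' @return data.frame with columns `ncrna_id`, `category`, `supporting`
#'   (comma-separated subset of `positive_start`, `coding_potential`,
#'   `rbs`, `small_orf_lt50aa`), `n_overlapping_orfs`.
#' @export
classify_ncrna_overlap <- function(ncrnas, orfs, scores = NULL,
                                   small_orf_aa = 50) {
  check_features(ncrnas, "classify_ncrna_overlap")
  orfs$start_score <- NA_real_
  orfs$coding_score <- NA_real_
  if (!is.null(scores) && nrow(scores) > 0) {
    okey <- paste(orfs$contig, orfs$start, orfs$end, orfs$strand)
    skey <- paste(scores$contig, scores$start, scores$end, scores$strand)
    idx <- match(skey, okey)
    if (anyNA(idx)) {
      stop("classify_ncrna_overlap: score row(s) reference coordinates ",
           "absent from the enumerated ORFs: ",
           paste(utils::head(skey[is.na(idx)], 3), collapse = "; "))
    }
    orfs$start_score[idx] <- scores$start_score
    orfs$coding_score[idx] <- scores$coding_score
  }
  if (!"has_rbs" %in% names(orfs)) orfs$has_rbs <- FALSE

  ngr <- gr_from_intervals(ncrnas)
  ogr <- gr_from_intervals(orfs)
  hits <- GenomicRanges::findOverlaps(ngr, ogr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  by_ncrna <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  res <- lapply(seq_len(nrow(ncrnas)), function(i) {
    oi <- by_ncrna[[as.character(i)]]
    if (is.null(oi) || length(oi) == 0) {
      return(data.frame(ncrna_id = ncrnas$id[i], category = "no_possible_orf",
                        supporting = "", n_overlapping_orfs = 0L,
                        stringsAsFactors = FALSE))
    }
    ov <- orfs[oi, , drop = FALSE]
    supporting <- character(0)
    if (any(!is.na(ov$start_score) & ov$start_score > 0)) {
      supporting <- c(supporting, "positive_start")
    }
    if (any(!is.na(ov$coding_score) & ov$coding_score > 0)) {
      supporting <- c(supporting, "coding_potential")
    }
    if (any(ov$has_rbs)) supporting <- c(supporting, "rbs")
    if (any(ov$length_aa < small_orf_aa)) {
      supporting <- c(supporting, "small_orf_lt50aa")
    }
    category <- if (length(supporting) > 0) "orf_with_support" else
      "possible_orf_only"
    data.frame(ncrna_id = ncrnas$id[i], category = category,
               supporting = paste(supporting, collapse = ","),
               n_overlapping_orfs = length(oi), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
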