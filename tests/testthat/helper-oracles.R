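# Independent brute-force oracles. Deliberately naive (per-record loops,
# character-level scans): they share no code with the package internals.

oracle_parse_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    data.frame(contig = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
               strand = f[6], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# all-pairs overlap counting on half-open intervals
oracle_count_overlaps <- function(reads, features) {
  vapply(seq_len(nrow(features)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(reads))) {
      if (reads$contig[j] == features$contig[i] &&
          reads$start[j] < features$end[i] &&
          reads$end[j] > features$start[i]) {
        n <- n + 1L
      }
    }
    n
  }, integer(1))
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# three-nested-loop six-frame ORF scan; returns 0-based forward-strand coords
oracle_orf_scan <- function(seq_chr, min_len) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_chr else oracle_revcomp(seq_chr)
    L <- nchar(s)
    for (i in 0:(L - 3)) {
      if (!substr(s, i + 1, i + 3) %in% starts) next
      j <- i + 3
      while (j + 3 <= L) {
        cod <- substr(s, j + 1, j + 3)
        if (cod %in% stops) {
          len <- j + 3 - i
          if (len >= min_len && !grepl("N", substr(s, i + 1, j + 3))) {
            if (strand == "+") {
              rows[[length(rows) + 1]] <- data.frame(
                start = i, end = j + 3, strand = "+")
            } else {
              rows[[length(rows) + 1]] <- data.frame(
                start = L - (j + 3), end = L - i, strand = "-")
            }
          }
          break
        }
        j <- j + 3
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# per-read tally of 5'/3' ends for fully contained oriented reads
oracle_end_profile <- function(reads, feature) {
  L <- feature$end - feature$start
  five <- integer(L); three <- integer(L); depth <- integer(L)
  for (j in seq_len(nrow(reads))) {
    r <- reads[j, ]
    if (r$contig != feature$contig || !r$strand %in% c("+", "-")) next
    if (r$start < feature$start || r$end > feature$end) next
    g5 <- if (r$strand == "+") r$start else r$end - 1
    g3 <- if (r$strand == "+") r$end - 1 else r$start
    rel <- function(g) {
      if (feature$strand == "+") g - feature$start else feature$end - 1 - g
    }
    five[rel(g5) + 1] <- five[rel(g5) + 1] + 1L
    three[rel(g3) + 1] <- three[rel(g3) + 1] + 1L
    for (g in r$start:(r$end - 1)) depth[rel(g) + 1] <- depth[rel(g) + 1] + 1L
  }
  list(five_prime = five, three_prime = three, depth = depth)
}

oracle_junctions <- function(mask) {
  pos <- integer(0)
  for (i in 2:length(mask)) {
    if (mask[i] != mask[i - 1]) pos <- c(pos, i - 1L)  # 0-based
  }
  pos
}

# definition check at every position: floor, strictly greater than the left
# window, at least the right window
oracle_peaks <- function(counts, min_count, window) {
  L <- length(counts)
  pos <- integer(0)
  for (i in seq_len(L)) {
    if (counts[i] < min_count) next
    ok <- TRUE
    for (j in max(1, i - window):min(L, i + window)) {
      if (j < i && counts[j] >= counts[i]) ok <- FALSE
      if (j > i && counts[j] > counts[i]) ok <- FALSE
    }
    if (ok) pos <- c(pos, i - 1L)
  }
  pos
}

# exact circular-shift null by enumerating every offset
oracle_exact_junction_null <- function(peaks, junctions, L, tolerance) {
  circ_hit <- function(p) {
    any(pmin(abs(p - junctions), L - abs(p - junctions)) <= tolerance)
  }
  stat_at <- function(off) {
    mean(vapply((peaks + off) %% L, circ_hit, logical(1)))
  }
  stats <- vapply(0:(L - 1), stat_at, numeric(1))
  list(observed = stats[1], exact_p = mean(stats >= stats[1]))
}
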