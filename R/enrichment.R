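# Structure junctions, end-profile peak calling, and circular-permutation
# enrichment tests (peak/junction association; CRISPR repeat vs spacer
# signal partitioning).
#
# Both tests use a circular-rotation null: rather than resampling positions
# uniformly, the observed configuration is rotated around the feature by a
# uniform random offset. This preserves the spacing structure of the peaks
# (or of the depth vector) and is therefore the stricter null.

#' Junctions of a secondary structure
#'
#' A junction is the first position whose paired state differs from its
#' predecessor: the boundary between a stem and a loop/linker. Positions
#' are 0-based and lie in `[1, length - 1]`.
#'
#' @param structure a [structure_annotation()].
#' @return object of class `junction_set`: list with `feature_id`,
#'   `positions` (sorted 0-based integer vector), `length`.
#' @export
#' @examples
#' s <- structure_annotation("x", "GGGGAAAACCCC", "((((....))))")
#' junctions_from_dotbracket(s)$positions  # 4 8
junctions_from_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "structure_annotation"))
  m <- structure$paired_mask
  L <- length(m)
  positions <- if (L < 2) integer(0) else which(m[-1] != m[-L])
  structure(
    list(feature_id = structure$feature_id,
         positions = as.integer(positions), length = L),
    class = "junction_set"
  )
}

#' Call peaks in an end profile
#'
#' Position `i` is a peak when its count reaches the floor `min_count`,
#' strictly exceeds every count in the `window` positions to its left, and
#' is at least every count in the `window` positions to its right. The
#' asymmetric tie rule makes the leftmost position of a tied run the one
#' reported, and the output deterministic.
#'
#' The default floor is depth-adaptive: `max(5, ceiling(2 * mean count))`.
#' A fixed absolute floor cannot separate signal from noise once the mean
#' end density of the profile exceeds it, which happens for any feature
#' with more reads than about 5 per position; scaling the floor with depth
#' keeps peak calls meaningful at every coverage. Pass an explicit
#' `min_count` to override.
#'
#' @param profile an `end_profile` (or a bare integer vector of counts).
#' @param end_type which array to call peaks in: `"five_prime"` or
#'   `"three_prime"` (ignored for a bare vector).
#' @param min_count minimum count for a peak; `NULL` (default) uses the
#'   depth-adaptive floor described above.
#' @param window flanking half-width in nt for the local-maximum test
#'   (default 2).
#' @return object of class `peak_set`: list with `feature_id`, `end_type`,
#'   `positions` (sorted 0-based), `heights`, `min_count`, `length`.
#' @export
call_peaks <- function(profile, end_type = c("five_prime", "three_prime"),
                       min_count = NULL, window = 2) {
  if (window < 0) stop("call_peaks: window must be >= 0")
  if (inherits(profile, "end_profile")) {
    end_type <- match.arg(end_type)
    counts <- profile[[end_type]]
    fid <- profile$feature_id
  } else {
    counts <- as.integer(profile)
    end_type <- if (identical(end_type, c("five_prime", "three_prime")))
      "counts" else end_type
    fid <- NA_character_
  }
  if (is.null(min_count)) {
    min_count <- max(5, ceiling(2 * sum(counts) / length(counts)))
  }
  if (min_count < 1) stop("call_peaks: min_count must be >= 1")
  L <- length(counts)
  pos <- integer(0)
  for (i in seq_len(L)) {
    if (counts[i] < min_count) next
    lo <- max(1L, i - window)
    hi <- min(L, i + window)
    left_ok <- lo > i - 1 || all(counts[lo:(i - 1)] < counts[i])
    right_ok <- hi < i + 1 || all(counts[(i + 1):hi] <= counts[i])
    if (left_ok && right_ok) pos <- c(pos, i - 1L)
  }
  structure(
    list(feature_id = fid, end_type = end_type,
         positions = as.integer(pos),
         heights = counts[pos + 1L],
         min_count = as.integer(min_count), length = L),
    class = "peak_set"
  )
}

#' Pool 5' and 3' peaks in cut-bond coordinates
#'
#' A nuclease cut at bond `b` (between positions `b - 1` and `b`) leaves a
#' 3' end at `b - 1` and a 5' end at `b`: both end types estimate the same
#' cut site. This pools the two peak sets on the common bond coordinate
#' (5' peak position as-is, 3' peak position + 1), which places peaks
#' caused by junction-adjacent cuts exactly on the junction positions.
#'
#' @param five,three `peak_set`s for the two end types of one profile.
#' @return a `peak_set` with `end_type = "cut_site"`; heights are the sums
#'   of the contributing peak heights at each pooled bond.
#' @export
pool_cut_site_peaks <- function(five, three) {
  stopifnot(inherits(five, "peak_set"), inherits(three, "peak_set"))
  if (five$length != three$length) {
    stop("pool_cut_site_peaks: peak sets span different lengths")
  }
  L <- five$length
  bond3 <- (three$positions + 1L) %% L
  pos <- sort(unique(c(five$positions, bond3)))
  h <- vapply(pos, function(p) {
    sum(five$heights[five$positions == p]) + sum(three$heights[bond3 == p])
  }, numeric(1))
  structure(
    list(feature_id = five$feature_id, end_type = "cut_site",
         positions = as.integer(pos), heights = as.integer(h),
         min_count = min(five$min_count, three$min_count), length = L),
    class = "peak_set"
  )
}

#' Full peak/junction test for one profile
#'
#' The package's headline junction analysis for a feature: calls 5' and 3'
#' peaks, pools them in cut-bond coordinates ([pool_cut_site_peaks()]),
#' tests the pooled set against the structure's junctions by circular
#' permutation, and reports junction recovery (the fraction of junctions
#' with a called peak of either end type within `recovery_tolerance` nt).
#' Because pooled peaks live on exact bond coordinates, the default match
#' tolerance for the test is 0 nt, which gives the sharpest circular null.
#'
#' @param profile an `end_profile`.
#' @param junctions a `junction_set` (or a [structure_annotation()], from
#'   which junctions are extracted).
#' @param tolerance match tolerance in nt for the pooled test (default 0).
#' @param recovery_tolerance tolerance in nt for junction recovery
#'   (default 2).
#' @param min_count,window peak-calling parameters, see [call_peaks()].
#' @param n_perm,seed permutation-test parameters, see
#'   [junction_enrichment()].
#' @return list with `enrichment` (an `enrichment_result`), `peaks`
#'   (the pooled `peak_set`), `five_prime`/`three_prime` (per-end
#'   `peak_set`s), `junction_recovery` (fraction in `[0, 1]`),
#'   `n_junctions`.
#' @export
profile_junction_test <- function(profile, junctions, tolerance = 0,
                                  recovery_tolerance = 2, min_count = NULL,
                                  window = 2, n_perm = 1000, seed = 17) {
  if (inherits(junctions, "structure_annotation")) {
    junctions <- junctions_from_dotbracket(junctions)
  }
  stopifnot(inherits(profile, "end_profile"),
            inherits(junctions, "junction_set"))
  pk5 <- call_peaks(profile, "five_prime", min_count = min_count,
                    window = window)
  pk3 <- call_peaks(profile, "three_prime", min_count = min_count,
                    window = window)
  pooled <- pool_cut_site_peaks(pk5, pk3)
  er <- junction_enrichment(pooled, junctions, tolerance = tolerance,
                            n_perm = n_perm, seed = seed)
  raw <- sort(unique(c(pk5$positions, pk3$positions)))
  recovery <- if (length(junctions$positions) == 0) NA_real_ else {
    mean(vapply(junctions$positions, function(j) {
      length(raw) > 0 && min(abs(raw - j)) <= recovery_tolerance
    }, logical(1)))
  }
  list(enrichment = er, peaks = pooled, five_prime = pk5, three_prime = pk3,
       junction_recovery = recovery,
       n_junctions = length(junctions$positions))
}

# Shared constructor for permutation-test results.
enrichment_result <- function(statistic, null_stats, n_perm, seed, tolerance) {
  p <- (1 + sum(null_stats >= statistic)) / (n_perm + 1)
  structure(
    list(statistic = statistic, null_mean = mean(null_stats),
         p_value = p, n_perm = as.integer(n_perm), seed = as.integer(seed),
         tolerance = as.integer(tolerance)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: statistic = %.4f (null mean %.4f), p = %.4g [%d permutations, seed %d]\n",
    x$statistic, x$null_mean, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Test peak/junction association by circular permutation
#'
#' The statistic is the fraction of peaks lying within `tolerance` nt
#' (circular distance) of any junction. The null distribution is obtained
#' by rotating all peak positions together by a uniform random offset,
#' `n_perm` times; the p-value is `(1 + #{null >= observed}) / (n_perm + 1)`,
#' so its floor is `1 / (n_perm + 1)`.
#'
#' @param peaks a `peak_set` from [call_peaks()].
#' @param junctions a `junction_set` from [junctions_from_dotbracket()].
#' @param tolerance maximum distance in nt for a peak to count as "at" a
#'   junction (default 2).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the offsets (default 17).
#' @return an `enrichment_result` with fields `statistic`, `null_mean`,
#'   `p_value`, `n_perm`, `seed`, `tolerance`.
#' @export
junction_enrichment <- function(peaks, junctions, tolerance = 2,
                                n_perm = 1000, seed = 17) {
  stopifnot(inherits(peaks, "peak_set"), inherits(junctions, "junction_set"))
  if (length(peaks$positions) == 0) stop("no peaks to test")
  if (length(junctions$positions) == 0) {
    stop("junction_enrichment: no junctions to test against")
  }
  L <- peaks$length
  if (junctions$length != L) {
    stop("junction_enrichment: peak and junction sets span different lengths")
  }
  # near[k + 1]: is 0-based position k within `tolerance` of a junction,
  # on the circle of circumference L
  near <- logical(L)
  for (j in junctions$positions) {
    k <- (j + (-tolerance:tolerance)) %% L
    near[k + 1L] <- TRUE
  }
  stat_at <- function(offset) mean(near[((peaks$positions + offset) %% L) + 1L])
  observed <- stat_at(0L)
  set.seed(seed)
  offsets <- sample.int(L, n_perm, replace = TRUE) - 1L
  null_stats <- vapply(offsets, stat_at, numeric(1))
  enrichment_result(observed, null_stats, n_perm, seed, tolerance)
}

#' Parse CRISPR arrays from a minCED-style GFF
#'
#' Reads `repeat_region`/`repeat_unit`/`direct_repeat` rows (the dialect
#' minCED emits within Prokka), groups them into arrays by their `ID`
#' attribute (falling back to one array per contig when absent), and
#' derives spacers as the gaps between consecutive repeats — minCED
#' reports repeats only.
#'
#' @param path GFF file.
#' @return list of `crispr_array` objects: each a list with `array_id`,
#'   `contig`, `span` (single-row interval), `repeats` and `spacers`
#'   (interval data.frames), `n_repeats`.
#' @export
parse_crispr_gff <- function(path) {
  if (!file.exists(path)) stop("CRISPR GFF not found: ", path)
  n_rows <- length(grep("^[^#]", readLines(path), value = TRUE))
  if (n_rows == 0) return(list())
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("repeat_region", "repeat_unit", "direct_repeat")
  gr <- gr[keep]
  if (length(gr) == 0) return(list())
  df <- intervals_from_gr(gr)
  df$array_id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  df$array_id[is.na(df$array_id)] <- paste0("array_", df$contig[is.na(df$array_id)])
  out <- lapply(split(df, df$array_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("parse_crispr_gff: overlapping repeats in array '", d$array_id[1], "'")
    }
    if (nrow(d) == 1) {
      warning("parse_crispr_gff: array '", d$array_id[1],
              "' has a single repeat; no spacers derivable")
    }
    repeats <- data.frame(contig = d$contig, start = d$start, end = d$end,
                          strand = d$strand, stringsAsFactors = FALSE)
    spacers <- if (nrow(d) > 1) {
      data.frame(contig = d$contig[-1], start = d$end[-nrow(d)],
                 end = d$start[-1], strand = d$strand[-1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    }
    crispr_array(d$array_id[1], repeats, spacers)
  })
  names(out) <- NULL
  out[order(vapply(out, function(a) a$array_id, character(1)))]
}

# Construct and validate a crispr_array object from repeat/spacer tables.
crispr_array <- function(array_id, repeats, spacers) {
  check_intervals(repeats, "crispr_array repeats")
  if (nrow(spacers) > 0) check_intervals(spacers, "crispr_array spacers")
  if (nrow(spacers) > 0 && nrow(spacers) != nrow(repeats) - 1) {
    stop("crispr_array: repeats and spacers must alternate")
  }
  span <- data.frame(contig = repeats$contig[1],
                     start = min(repeats$start), end = max(repeats$end),
                     strand = repeats$strand[1], stringsAsFactors = FALSE)
  structure(
    list(array_id = array_id, contig = repeats$contig[1], span = span,
         repeats = repeats, spacers = spacers, n_repeats = nrow(repeats)),
    class = "crispr_array"
  )
}

#' @export
print.crispr_array <- function(x, ...) {
  cat("crispr_array '", x$array_id, "': ", x$n_repeats, " repeats over ",
      x$span$contig, ":", x$span$start, "-", x$span$end, "\n", sep = "")
  invisible(x)
}

#' Partition signal between CRISPR repeats and spacers
#'
#' The statistic is the fraction of total signal (summed depth) falling
#' inside repeat intervals; under uniform coverage it equals the
#' repeat-length fraction of the array. The null rotates the depth vector
#' circularly by uniform random offsets. Each repeat is additionally
#' flagged "signal-positive" when its mean depth reaches `min_mean_depth`.
#'
#' @param depth numeric vector of per-position coverage over the array
#'   span (element `i` = 0-based span-relative position `i - 1`).
#' @param array a `crispr_array`.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (default 17).
#' @param min_mean_depth per-repeat mean-depth cutoff for the
#'   signal-positive flag (default 1).
#' @return list with `enrichment` (an `enrichment_result`), `repeats`
#'   (per-repeat table: `start`, `end`, `mean_depth`, `signal_positive`),
#'   `n_signal_positive`, `repeat_length_fraction`.
#' @export
repeat_spacer_partition <- function(depth, array, n_perm = 1000, seed = 17,
                                    min_mean_depth = 1) {
  stopifnot(inherits(array, "crispr_array"))
  L <- array$span$end - array$span$start
  if (length(depth) != L) {
    stop("repeat_spacer_partition: depth length ", length(depth),
         " does not match array span ", L)
  }
  total <- sum(depth)
  if (total == 0) stop("no signal over array")
  # span-relative repeat mask
  mask <- logical(L)
  rel_s <- array$repeats$start - array$span$start
  rel_e <- array$repeats$end - array$span$start
  for (i in seq_along(rel_s)) mask[(rel_s[i] + 1):rel_e[i]] <- TRUE
  stat_at <- function(offset) {
    idx <- ((which(mask) - 1L + offset) %% L) + 1L
    sum(depth[idx]) / total
  }
  observed <- sum(depth[mask]) / total
  set.seed(seed)
  offsets <- sample.int(L, n_perm, replace = TRUE) - 1L
  null_stats <- vapply(offsets, stat_at, numeric(1))
  res <- enrichment_result(observed, null_stats, n_perm, seed, tolerance = 0)

  mean_depth <- vapply(seq_along(rel_s), function(i) {
    mean(depth[(rel_s[i] + 1):rel_e[i]])
  }, numeric(1))
  repeats <- data.frame(
    repeat_index = seq_along(rel_s),
    start = array$repeats$start, end = array$repeats$end,
    mean_depth = mean_depth,
    signal_positive = mean_depth >= min_mean_depth
  )
  list(enrichment = res, repeats = repeats,
       n_signal_positive = sum(repeats$signal_positive),
       repeat_length_fraction = sum(mask) / L)
}

#' Per-position depth over an arbitrary interval
#'
#' Coverage of `interval` by `reads` (any overlap, strand-agnostic), as a
#' plain vector suitable for [repeat_spacer_partition()] or
#' [write_bedgraph()].
#'
#' @param reads internal alignment table.
#' @param interval single-row interval data.frame.
#' @return integer vector of length `interval$end - interval$start`.
#' @export
depth_over_interval <- function(reads, interval) {
  check_intervals(interval, "depth_over_interval")
  if (nrow(interval) != 1) stop("depth_over_interval: single interval required")
  L <- interval$end - interval$start
  depth <- integer(L)
  if (nrow(reads) == 0) return(depth)
  check_reads(reads, "depth_over_interval")
  r <- reads[reads$contig == interval$contig &
               reads$start < interval$end & reads$end > interval$start, ,
             drop = FALSE]
  if (nrow(r) == 0) return(depth)
  s <- pmax(r$start, interval$start) - interval$start
  e <- pmin(r$end, interval$end) - interval$start
  inc <- tabulate(s + 1L, nbins = L + 1L)
  dec <- tabulate(e + 1L, nbins = L + 1L)
  as.integer(cumsum(inc - dec)[seq_len(L)])
}
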