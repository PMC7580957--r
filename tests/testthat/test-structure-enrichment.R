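# Junction extraction, peak calling, and the circular-permutation tests.

test_that("junctions are the paired-state transitions", {
  s <- structure_annotation("x", "GGGGAAAACCCC", "((((....))))")
  expect_equal(junctions_from_dotbracket(s)$positions, c(4L, 8L))
  flat <- structure_annotation("y", strrep("A", 12), strrep(".", 12))
  expect_equal(junctions_from_dotbracket(flat)$positions, integer(0))
})

test_that("random structures give junctions equal to the adjacent-pair scan", {
  for (i in 1:200) {
    st <- simulate_structured_transcript(sample(60:150, 1), sample(1:3, 1),
                                         seed = i)
    got <- junctions_from_dotbracket(st)$positions
    expect_equal(got, oracle_junctions(st$paired_mask))
  }
})

test_that("peak calling honors the floor, local-maximum rule and leftmost ties", {
  pk <- call_peaks(c(0, 0, 9, 0, 0), min_count = 5)
  expect_equal(pk$positions, 2L)
  expect_equal(pk$heights, 9L)
  pk2 <- call_peaks(c(0, 7, 7, 0), min_count = 5, window = 2)
  expect_equal(pk2$positions, 1L)
  expect_error(call_peaks(c(1, 2), min_count = 0), "min_count")
})

test_that("peak calls equal the definition check at every position", {
  set.seed(51)
  for (i in 1:20) {
    counts <- rpois(100, lambda = sample(1:8, 1))
    mc <- sample(2:6, 1)
    w <- sample(1:4, 1)
    pk <- call_peaks(counts, min_count = mc, window = w)
    expect_equal(pk$positions, oracle_peaks(counts, mc, w))
  }
})

test_that("the adaptive default floor is max(5, twice the mean density)", {
  counts <- rep(10L, 100)
  pk <- call_peaks(counts)
  expect_equal(pk$min_count, 20L)
  pk2 <- call_peaks(c(9, rep(0L, 99)))
  expect_equal(pk2$min_count, 5L)
})

mk_peaks <- function(pos, L) {
  structure(list(feature_id = "f", end_type = "five_prime",
                 positions = as.integer(sort(pos)),
                 heights = rep(10L, length(pos)),
                 min_count = 5L, length = L),
            class = "peak_set")
}
mk_junc <- function(pos, L) {
  structure(list(feature_id = "f", positions = as.integer(sort(pos)),
                 length = L),
            class = "junction_set")
}

test_that("maximal and null associations hit the statistic extremes", {
  js <- mk_junc(c(10, 30), 60)
  on <- mk_peaks(c(10, 30), 60)
  er <- junction_enrichment(on, js, tolerance = 0, n_perm = 500, seed = 1)
  expect_equal(er$statistic, 1)
  expect_gte(er$p_value, 1 / 501)
  far <- mk_peaks(c(20, 50), 60)
  er2 <- junction_enrichment(far, js, tolerance = 0, n_perm = 500, seed = 1)
  expect_equal(er2$statistic, 0)
  expect_gt(er2$p_value, 0.5)
  expect_error(junction_enrichment(mk_peaks(integer(0), 60), js), "no peaks")
})

test_that("permutation p-values match exhaustive offset enumeration", {
  set.seed(52)
  for (i in 1:10) {
    L <- 20L
    peaks <- sample(0:(L - 1), 1)
    juncs <- sample(1:(L - 1), 2)
    er <- junction_enrichment(mk_peaks(peaks, L), mk_junc(juncs, L),
                              tolerance = 1, n_perm = 4000, seed = i)
    ex <- oracle_exact_junction_null(peaks, juncs, L, tolerance = 1)
    expect_equal(er$statistic, ex$observed)
    se <- sqrt(ex$exact_p * (1 - ex$exact_p) / 4000)
    expect_lt(abs(er$p_value - ex$exact_p), 3 * se + 2 / 4000)
  }
})

test_that("p-values respect their floor and ceiling on random inputs", {
  set.seed(53)
  for (i in 1:25) {
    L <- sample(30:100, 1)
    np <- sample(1:6, 1)
    er <- junction_enrichment(mk_peaks(sample(0:(L - 1), np), L),
                              mk_junc(sample(1:(L - 1), sample(1:5, 1)), L),
                              tolerance = sample(0:3, 1), n_perm = 99,
                              seed = i)
    expect_gte(er$p_value, 1 / 100)
    expect_lte(er$p_value, 1)
    expect_gte(er$statistic, 0)
    expect_lte(er$statistic, 1)
  }
})

test_that("the statistic is invariant to joint translation of peaks and junctions", {
  set.seed(54)
  L <- 80L
  peaks <- sample(0:(L - 1), 6)
  juncs <- sample(1:(L - 1), 4)
  base <- junction_enrichment(mk_peaks(peaks, L), mk_junc(juncs, L),
                              tolerance = 2, n_perm = 10, seed = 1)
  for (shift in c(5, 17, 40)) {
    moved <- junction_enrichment(
      mk_peaks((peaks + shift) %% L, L),
      mk_junc((juncs + shift) %% L, L),
      tolerance = 2, n_perm = 10, seed = 1)
    expect_equal(moved$statistic, base$statistic)
  }
})

test_that("uniform random peaks give nominal type-I error", {
  set.seed(55)
  hits <- 0L
  n_trials <- 400L
  for (i in seq_len(n_trials)) {
    L <- 200L
    peaks <- sample(0:(L - 1), 12)
    juncs <- sample(1:(L - 1), 8)
    er <- junction_enrichment(mk_peaks(peaks, L), mk_junc(juncs, L),
                              tolerance = 2, n_perm = 199, seed = i)
    if (er$p_value <= 0.05) hits <- hits + 1L
  }
  rate <- hits / n_trials
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("cut-site pooling aligns 3' peaks onto their cut bonds", {
  five <- mk_peaks(c(10, 20), 50)
  three <- structure(list(feature_id = "f", end_type = "three_prime",
                          positions = c(9L, 29L), heights = c(4L, 6L),
                          min_count = 5L, length = 50L),
                     class = "peak_set")
  pooled <- pool_cut_site_peaks(five, three)
  expect_equal(pooled$positions, c(10L, 20L, 30L))
  # the 3' peak at 9 shares bond 10 with the 5' peak at 10: heights add
  expect_equal(pooled$heights[pooled$positions == 10L], 14L)
})

test_that("minCED-style GFF parses into arrays with derived spacers", {
  gff <- c("##gff-version 3",
           sprintf("ctg\tminced:0.2.0\trepeat_region\t%d\t%d\t.\t.\t.\tID=CRISPR1;rpt_family=CRISPR",
                   c(101, 166, 231), c(130, 195, 260)))
  path <- write_lines_tmp(gff, ext = ".gff")
  arrays <- parse_crispr_gff(path)
  expect_equal(length(arrays), 1L)
  a <- arrays[[1]]
  expect_equal(a$n_repeats, 3L)
  expect_equal(nrow(a$spacers), 2L)
  expect_equal(a$spacers$end - a$spacers$start, c(35L, 35L))
  # repeats and spacers tile the span without gaps
  tiles <- rbind(a$repeats[, c("start", "end")], a$spacers[, c("start", "end")])
  tiles <- tiles[order(tiles$start), ]
  expect_equal(tiles$start[-1], tiles$end[-nrow(tiles)])

  empty <- write_lines_tmp("##gff-version 3", ext = ".gff")
  expect_equal(parse_crispr_gff(empty), list())
})

test_that("overlapping repeats error and single-repeat arrays warn", {
  bad <- c("##gff-version 3",
           "ctg\tm\trepeat_region\t101\t140\t.\t.\t.\tID=CRISPR1",
           "ctg\tm\trepeat_region\t120\t160\t.\t.\t.\tID=CRISPR1")
  expect_error(parse_crispr_gff(write_lines_tmp(bad, ext = ".gff")),
               "overlapping")
  single <- c("##gff-version 3",
              "ctg\tm\trepeat_region\t101\t140\t.\t.\t.\tID=CRISPR1")
  expect_warning(parse_crispr_gff(write_lines_tmp(single, ext = ".gff")),
                 "single repeat")
})

test_that("an 18-repeat simulated GFF recovers its layout through the parser", {
  sim <- simulate_crispr_array(18, seed = 5,
                               gff_path = tempfile(fileext = ".gff"))
  arrays <- parse_crispr_gff(sim$gff_path)
  expect_equal(length(arrays), 1L)
  expect_equal(arrays[[1]]$n_repeats, 18L)
  expect_equal(arrays[[1]]$repeats$start, sim$array$repeats$start)
  expect_equal(arrays[[1]]$repeats$end, sim$array$repeats$end)
})

test_that("repeat/spacer partitioning matches closed-form cases", {
  sim <- simulate_crispr_array(3, repeat_len = 30, spacer_len = 35, seed = 2)
  a <- sim$array
  L <- a$span$end - a$span$start
  # all signal inside repeats
  depth <- numeric(L)
  for (i in seq_len(nrow(a$repeats))) {
    rel <- (a$repeats$start[i] - a$span$start):(a$repeats$end[i] - a$span$start - 1)
    depth[rel + 1] <- 3
  }
  part <- repeat_spacer_partition(depth, a, n_perm = 200, seed = 1)
  expect_equal(part$enrichment$statistic, 1)
  # uniform depth: statistic is exactly the repeat-length fraction
  part_u <- repeat_spacer_partition(rep(2, L), a, n_perm = 200, seed = 1)
  expect_equal(part_u$enrichment$statistic, part_u$repeat_length_fraction)
  expect_gt(part_u$enrichment$p_value, 0.2)
  expect_error(repeat_spacer_partition(numeric(L), a), "no signal")
})

test_that("structure-protected digestion concentrates signal in repeats", {
  sim <- simulate_crispr_array(18, seed = 7)
  cfg <- digestion_config(seed = 8)
  dig <- digest(sim$structure, cfg)
  reads <- emit_reads(dig$fragments, cfg, sim$feature)
  depth <- depth_over_interval(reads, sim$array$span)
  part <- repeat_spacer_partition(depth, sim$array, n_perm = 999, seed = 9)
  expect_gt(part$enrichment$statistic, part$repeat_length_fraction)
  expect_lte(part$enrichment$p_value, 0.01)
})
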