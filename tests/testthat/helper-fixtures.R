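# Seeded random fixture builders shared across test files.

random_reads <- function(n, contig = "chr1", contig_len = 1000,
                         len_range = c(15, 40)) {
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(contig_len - l, 1L) - 1L,
                  integer(1))
  data.frame(contig = contig, start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             query_length = len, sample_id = "test",
             stringsAsFactors = FALSE)
}

random_features <- function(n, contig = "chr1", contig_len = 1000,
                            len_range = c(50, 150), biotype = "ncRNA") {
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(contig_len - l, 1L) - 1L,
                  integer(1))
  data.frame(id = sprintf("feat%d", seq_len(n)), contig = contig,
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = biotype, stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a ready-made digested transcript scenario used by several files
digested_transcript <- function(seed, length = 300, n_stems = 4,
                                config = digestion_config(seed = seed + 1000)) {
  st <- simulate_structured_transcript(length, n_stems, seed = seed)
  feat <- data.frame(id = "nc1", contig = "ctg", start = 100L,
                     end = 100L + st$length, strand = "+", biotype = "ncRNA",
                     stringsAsFactors = FALSE)
  dig <- digest(st, config)
  reads <- emit_reads(dig$fragments, config, feat)
  list(structure = st, feature = feat, digestion = dig, reads = reads,
       config = config)
}
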