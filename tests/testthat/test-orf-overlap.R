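# ORF enumeration, Shine-Dalgarno detection, and ncRNA overlap classes.

test_that("minimal and degenerate sequences enumerate correctly", {
  orfs <- enumerate_orfs(c(ctg = "ATGAAATAA"), min_len = 9)
  plus <- orfs[orfs$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 0L)
  expect_equal(plus$end, 9L)
  expect_equal(plus$length_nt, 9L)
  expect_equal(plus$length_aa, 2)
  expect_equal(plus$start_codon, "ATG")

  none <- enumerate_orfs(c(ctg = "CCCCCCCCC"), min_len = 9)
  expect_equal(nrow(none[none$strand == "+", ]), 0L)
})

test_that("random-sequence ORF sets match the brute-force six-frame scan", {
  set.seed(21)
  for (rep in 1:3) {
    seq_chr <- random_dna(500)
    orfs <- enumerate_orfs(c(c1 = seq_chr), min_len = 15)
    want <- oracle_orf_scan(seq_chr, 15)
    got <- orfs[order(orfs$start, orfs$end, orfs$strand),
                c("start", "end", "strand")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("ORFs containing N are skipped and invalid characters error", {
  seq_n <- "ATGANATAAATGAAATAA"
  orfs <- enumerate_orfs(c(c1 = seq_n), min_len = 9)
  expect_false(any(grepl("N", substring(rep(seq_n, nrow(orfs)),
                                        orfs$start + 1, orfs$end))))
  expect_error(enumerate_orfs(c(c1 = "ATGXXXTAA")), "non-nucleotide")
})

test_that("enumeration commutes with reverse complement (mirror coordinates)", {
  set.seed(22)
  seq_chr <- random_dna(400)
  L <- nchar(seq_chr)
  fwd <- enumerate_orfs(c(c1 = seq_chr), min_len = 15)
  rev <- enumerate_orfs(c(c1 = oracle_revcomp(seq_chr)), min_len = 15)
  mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$end, mirrored$strand), ]
  got <- fwd[order(fwd$start, fwd$end, fwd$strand),
             c("start", "end", "strand")]
  rownames(got) <- rownames(mirrored) <- NULL
  expect_equal(got, mirrored)
})

test_that("translations of enumerated ORFs contain no internal stop", {
  set.seed(23)
  seq_chr <- random_dna(600)
  orfs <- enumerate_orfs(c(c1 = seq_chr), min_len = 15)
  dna <- Biostrings::DNAString(seq_chr)
  for (i in seq_len(nrow(orfs))) {
    sub <- Biostrings::subseq(dna, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] == "-") sub <- Biostrings::reverseComplement(sub)
    aa <- as.character(Biostrings::translate(sub, no.init.codon = TRUE))
    # exactly one stop, at the end
    expect_equal(substring(aa, nchar(aa)), "*")
    expect_false(grepl("\\*", substring(aa, 1, nchar(aa) - 1)))
  }
})

test_that("raising min_len only removes ORFs", {
  set.seed(24)
  seq_chr <- random_dna(500)
  o15 <- enumerate_orfs(c(c1 = seq_chr), min_len = 15)
  o30 <- enumerate_orfs(c(c1 = seq_chr), min_len = 30)
  expect_true(all(o30$id %in% o15$id))
  expect_equal(o30$id, o15$id[o15$length_nt >= 30])
})

test_that("RBS detection respects the motif, mismatch budget and spacer range", {
  # AGGAGG + 7 nt spacer + ATG...
  seq_hit <- paste0("CCCC", "AGGAGG", "TTTTTTT", "ATGAAATAA", "CC")
  orfs <- enumerate_orfs(c(c1 = seq_hit), min_len = 9)
  orf <- orfs[orfs$strand == "+" & orfs$start_codon == "ATG", ][1, ]
  expect_true(find_rbs(c(c1 = seq_hit), orf))
  # spacer of 2 nt: below range
  seq_near <- paste0("CCCC", "AGGAGG", "TT", "ATGAAATAA", "CC")
  orfs2 <- enumerate_orfs(c(c1 = seq_near), min_len = 9)
  orf2 <- orfs2[orfs2$strand == "+" & orfs2$start_codon == "ATG", ][1, ]
  expect_false(find_rbs(c(c1 = seq_near), orf2))
})

test_that("planted RBS motifs are detected per the planting record", {
  set.seed(25)
  for (i in 1:100) {
    spacer <- sample(3:16, 1)
    n_mm <- sample(0:2, 1)
    motif <- strsplit("AGGAGG", "")[[1]]
    if (n_mm > 0) {
      idx <- sample(6, n_mm)
      for (k in idx) {
        motif[k] <- sample(setdiff(c("A", "C", "G", "T"), motif[k]), 1)
      }
    }
    # CCCC-only background cannot spuriously match AGGAGG within 1 mismatch
    seq_chr <- paste0(strrep("C", 20), paste(motif, collapse = ""),
                      strrep("C", spacer), "ATGAAATAA", strrep("C", 5))
    orfs <- enumerate_orfs(c(c1 = seq_chr), min_len = 9)
    orf <- orfs[orfs$strand == "+" & orfs$start_codon == "ATG", ][1, ]
    expected <- spacer >= 5 && spacer <= 13 && n_mm <= 1
    expect_identical(find_rbs(c(c1 = seq_chr), orf), expected)
  }
})

test_that("RBS detection is strand-aware on the reverse strand", {
  # reverse-complement of AGGAGG + 7 spacer + ATG..., planted on the - strand
  fwd <- paste0("CCCC", "AGGAGG", "TTTTTTT", "ATGAAATAA", "CC")
  rc <- oracle_revcomp(fwd)
  orfs <- enumerate_orfs(c(c1 = rc), min_len = 9)
  orf <- orfs[orfs$strand == "-" & orfs$start_codon == "ATG", ][1, ]
  expect_true(find_rbs(c(c1 = rc), orf))
})

test_that("ncRNA overlap classification covers the three categories", {
  orfs <- data.frame(
    id = c("o1", "o2"), contig = "chr1",
    start = c(100L, 500L), end = c(130L, 800L), strand = "+",
    frame = 0L, start_codon = "ATG",
    length_nt = c(30L, 300L), length_aa = c(9, 99),
    has_rbs = FALSE, stringsAsFactors = FALSE)
  ncrnas <- data.frame(
    id = c("ncA", "ncB", "ncC"), contig = "chr1",
    start = c(90L, 550L, 2000L), end = c(140L, 700L, 2100L),
    strand = "+", biotype = "ncRNA", stringsAsFactors = FALSE)
  cls <- classify_ncrna_overlap(ncrnas, orfs)
  expect_equal(cls$category,
               c("orf_with_support", "possible_orf_only", "no_possible_orf"))
  expect_equal(cls$supporting, c("small_orf_lt50aa", "", ""))
})

test_that("Prodigal scores join by coordinates and unknown coordinates error", {
  orfs <- data.frame(
    id = "o1", contig = "chr1", start = 100L, end = 130L, strand = "+",
    frame = 0L, start_codon = "ATG", length_nt = 30L, length_aa = 9,
    has_rbs = FALSE, stringsAsFactors = FALSE)
  ncrnas <- data.frame(id = "ncA", contig = "chr1", start = 90L, end = 140L,
                       strand = "+", biotype = "ncRNA",
                       stringsAsFactors = FALSE)
  scores <- data.frame(orf_id = "x", contig = "chr1", start = 100L,
                       end = 130L, strand = "+", start_score = 2.5,
                       coding_score = -1, rbs_motif = "",
                       stringsAsFactors = FALSE)
  cls <- classify_ncrna_overlap(ncrnas, orfs, scores)
  expect_true(grepl("positive_start", cls$supporting))
  expect_false(grepl("coding_potential", cls$supporting))

  bad <- scores
  bad$start <- 999L
  expect_error(classify_ncrna_overlap(ncrnas, orfs, bad), "absent")
})

test_that("planted ORFs of each support class classify per the planting record", {
  set.seed(26)
  # build a genome with 4 ncRNAs, each overlapped by a distinct ORF class
  mk_orf <- function(n_codons) {
    body <- sample(setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), n_codons, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  big <- mk_orf(60)    # 62 aa: not small
  small <- mk_orf(8)   # 9 aa: small
  spacer <- strrep("C", 50)
  genome <- paste0(spacer, big, spacer, small, spacer)
  s_big <- nchar(spacer)
  s_small <- nchar(spacer) * 2 + nchar(big)
  ncrnas <- data.frame(
    id = c("over_big", "over_small", "over_none"),
    contig = "g",
    start = c(s_big + 3L, s_small + 3L, nchar(genome) - 30L),
    end = c(s_big + 40L, s_small + 20L, nchar(genome) - 10L),
    strand = "+", biotype = "ncRNA", stringsAsFactors = FALSE)
  orfs <- enumerate_orfs(c(g = genome), min_len = 15)
  orfs$has_rbs <- FALSE
  cls <- classify_ncrna_overlap(ncrnas, orfs)
  expect_equal(cls$category[cls$ncrna_id == "over_small"], "orf_with_support")
  expect_equal(cls$category[cls$ncrna_id == "over_none"], "no_possible_orf")
  # the big ORF carries no score/RBS and is >= 50 aa, but nested starts
  # within it can be small; accept either non-empty category consistently
  big_cls <- cls[cls$ncrna_id == "over_big", ]
  expect_true(big_cls$category %in% c("possible_orf_only", "orf_with_support"))
  expect_gte(big_cls$n_overlapping_orfs, 1L)
})
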