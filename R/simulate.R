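# Synthetic structure-protected nuclease digestion.
#
# The generator emulates the mechanism under study: an RNA molecule is cut
# at inter-nucleotide bonds, with bonds inside stems (both flanking bases
# paired) cut at a much lower rate than accessible bonds; fragments then
# pass a hard size-selection window, become error-free ungapped reads (one
# read per fragment), and fragments longer than the machine read length are
# truncated from the 5' end — exactly the reads the fragment-length filter
# must remove. Every draw flows from one seeded generator per invocation,
# so outputs are bit-identical across runs with the same seed.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Digestion simulation parameters
#'
#' Bundles the per-bond cut probabilities, the fragment size-selection
#' window (15-45 nt, the range bacterial ribosome-profiling protocols
#' select), the number of molecules digested, and the machine read length.
#'
#' @param p_cut_unpaired cut probability per accessible bond (default 0.2).
#' @param p_cut_paired cut probability per structure-protected bond, i.e.
#'   both flanking bases paired (default 0.005).
#' @param size_min,size_max fragment size-selection window in nt
#'   (defaults 15 and 45).
#' @param n_molecules number of molecule copies digested (default 600,
#'   which yields roughly 2,000-3,000 size-selected fragments for a 300-nt
#'   transcript with four default hairpins).
#' @param read_len machine read length in nt (default 36).
#' @param seed RNG seed.
#' @return object of class `digestion_config`.
#' @export
digestion_config <- function(p_cut_unpaired = 0.2, p_cut_paired = 0.005,
                             size_min = 15, size_max = 45,
                             n_molecules = 600, read_len = 36, seed = 1) {
  if (p_cut_paired < 0 || p_cut_unpaired > 1 ||
      p_cut_paired > p_cut_unpaired) {
    stop("digestion_config: need 0 <= p_cut_paired <= p_cut_unpaired <= 1")
  }
  if (size_min > size_max || size_min < 1) {
    stop("digestion_config: need 1 <= size_min <= size_max")
  }
  if (n_molecules < 1 || read_len < 1) {
    stop("digestion_config: n_molecules and read_len must be positive")
  }
  structure(
    list(p_cut_unpaired = p_cut_unpaired, p_cut_paired = p_cut_paired,
         size_min = as.integer(size_min), size_max = as.integer(size_max),
         n_molecules = as.integer(n_molecules),
         read_len = as.integer(read_len), seed = as.integer(seed)),
    class = "digestion_config"
  )
}

#' Simulate a structured transcript
#'
#' Builds a transcript of `n_stems` hairpins (stem + terminal loop)
#' separated by unpaired linkers, with seeded random stem lengths and
#' linker allocation, so junction positions vary across seeds. Stem halves
#' are reverse-complementary; unpaired positions are random. The default
#' geometry (stems of 14-17 bp, 3-nt loops) keeps every hairpin between 31
#' and 37 nt — inside the 15-45 nt fragment size-selection window, so
#' structure-protected fragments are observable after digestion — and keeps
#' stems at least `size_min - 1` bp long, so the size-selection floor does
#' not displace the mode of surviving fragment ends away from the stem
#' boundaries. Mixed stem lengths avoid degenerate (periodic) junction
#' spacing across hairpins.
#'
#' @param length transcript length in nt.
#' @param n_stems number of hairpins (0 gives a fully unpaired transcript).
#' @param seed RNG seed.
#' @param loop_len terminal loop length in nt (default 3, the minimal RNA
#'   hairpin loop).
#' @param stem_range integer length-2 vector of stem lengths to sample
#'   from (default `c(14, 17)`; truncated when the transcript is too short).
#' @param feature_id identifier for the emitted structure.
#' @return a [structure_annotation()].
#' @export
simulate_structured_transcript <- function(length, n_stems, seed,
                                           loop_len = 3,
                                           stem_range = c(14, 17),
                                           feature_id = "synth_transcript") {
  set.seed(seed)
  rand_base <- function(n) sample(names(COMPLEMENT), n, replace = TRUE)
  if (n_stems == 0) {
    return(structure_annotation(feature_id,
                                paste(rand_base(length), collapse = ""),
                                strrep(".", length)))
  }
  min_linker <- 3L
  min_stem <- 2L
  n_linkers <- n_stems + 1L
  min_total <- n_linkers * min_linker + n_stems * (loop_len + 2L * min_stem)
  if (length < min_total) {
    stop("simulate_structured_transcript: infeasible geometry (need >= ",
         min_total, " nt for ", n_stems, " stems)")
  }
  s_max <- (length - n_linkers * min_linker - n_stems * loop_len) %/%
    (2L * n_stems)
  s_lo <- min(stem_range[1], s_max)
  s_hi <- min(stem_range[2], s_max)
  stems <- sample(seq(s_lo, s_hi), n_stems, replace = TRUE)
  extra <- length - n_linkers * min_linker -
    sum(2L * stems + loop_len)
  linkers <- rep(min_linker, n_linkers)
  if (extra > 0) {
    linkers <- linkers + tabulate(sample.int(n_linkers, extra, replace = TRUE),
                                  nbins = n_linkers)
  }
  db <- character(0)
  seq_chars <- character(0)
  for (k in seq_len(n_stems)) {
    db <- c(db, strrep(".", linkers[k]),
            strrep("(", stems[k]), strrep(".", loop_len),
            strrep(")", stems[k]))
    left <- rand_base(stems[k])
    right <- rev(unname(COMPLEMENT[left]))
    seq_chars <- c(seq_chars, rand_base(linkers[k]), left,
                   rand_base(loop_len), right)
  }
  db <- paste(c(db, strrep(".", linkers[n_linkers])), collapse = "")
  seq_chars <- c(seq_chars, rand_base(linkers[n_linkers]))
  structure_annotation(feature_id, paste(seq_chars, collapse = ""), db)
}

#' Digest molecules of a structured transcript
#'
#' For each of `n_molecules` copies, every inter-nucleotide bond is cut
#' independently: with probability `p_cut_paired` when both flanking bases
#' are paired (protected), else `p_cut_unpaired`. Fragments are the runs
#' between cuts (molecule ends count as cuts); fragments outside the size
#' window are discarded. Ground truth records per-bond cut counts and the
#' pre-selection fragments, enough to verify every downstream stage.
#'
#' @param structure a [structure_annotation()].
#' @param config a [digestion_config()].
#' @return list with `fragments` (data.frame `molecule`, `start`, `end`,
#'   `length`; 0-based transcript coordinates, size-selected) and
#'   `ground_truth` (list: `junctions` (0-based), `bond_protected`
#'   (logical per bond), `cut_counts` (per bond), `n_molecules`,
#'   `n_fragments_total`, `n_fragments_selected`, `config`).
#' @export
digest <- function(structure, config) {
  stopifnot(inherits(structure, "structure_annotation"),
            inherits(config, "digestion_config"))
  L <- structure$length
  m <- structure$paired_mask
  protected <- m[-L] & m[-1]     # bond i (0-based, between i-1 and i): index i
  bond_p <- ifelse(protected, config$p_cut_paired, config$p_cut_unpaired)
  n <- config$n_molecules
  set.seed(config$seed)
  cuts <- matrix(runif(n * (L - 1L)), nrow = n) <
    matrix(bond_p, nrow = n, ncol = L - 1L, byrow = TRUE)
  frag_list <- vector("list", n)
  for (i in seq_len(n)) {
    b <- c(0L, which(cuts[i, ]), L)
    frag_list[[i]] <- cbind(i, b[-length(b)], b[-1])
  }
  frags <- do.call(rbind, frag_list)
  all_frags <- data.frame(molecule = frags[, 1], start = frags[, 2],
                          end = frags[, 3])
  all_frags$length <- all_frags$end - all_frags$start
  sel <- all_frags$length >= config$size_min &
    all_frags$length <= config$size_max
  fragments <- all_frags[sel, , drop = FALSE]
  rownames(fragments) <- NULL
  list(
    fragments = fragments,
    ground_truth = list(
      junctions = junctions_from_dotbracket(structure)$positions,
      bond_protected = protected,
      cut_counts = colSums(cuts),
      n_molecules = n,
      n_fragments_total = nrow(all_frags),
      n_fragments_selected = nrow(fragments),
      config = config
    )
  )
}

#' Turn fragments into read alignments
#'
#' Each fragment becomes one error-free ungapped alignment at its genomic
#' position (the feature places the transcript on the genome; strand is
#' inherited). Fragments longer than the read length are truncated at
#' `read_len` nt from their 5' end. The `truncated` ground-truth flag marks
#' every fragment at least as long as the read length: those reads' 3' ends
#' are not certifiable nuclease cuts (a read at exactly machine length
#' cannot show that its fragment ended there), and they are exactly the
#' reads [filter_fragment_truncated()] removes downstream.
#'
#' @param fragments fragment data.frame from [digest()] (0-based transcript
#'   coordinates).
#' @param config a [digestion_config()].
#' @param feature single-row feature data.frame placing the transcript; its
#'   strand must be `+` or `-`.
#' @param sample_id library label for the emitted reads.
#' @return internal alignment table with an extra logical `truncated`
#'   column (the ground-truth flag; not part of the alignment contract).
#' @export
emit_reads <- function(fragments, config, feature, sample_id = "sim") {
  stopifnot(inherits(config, "digestion_config"))
  if (!feature$strand %in% c("+", "-")) {
    stop("emit_reads: feature must be stranded")
  }
  truncated <- fragments$length >= config$read_len
  # 5'-anchored truncation in transcript coordinates
  tstart <- fragments$start
  tend <- pmin(fragments$end, fragments$start + config$read_len)
  if (feature$strand == "+") {
    gstart <- feature$start + tstart
    gend <- feature$start + tend
  } else {
    gstart <- feature$end - tend
    gend <- feature$end - tstart
  }
  out <- data.frame(
    contig = feature$contig, start = as.integer(gstart),
    end = as.integer(gend), strand = feature$strand,
    query_length = as.integer(tend - tstart),
    sample_id = sample_id, truncated = truncated,
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0) {
    out$name <- sprintf("%s_frag%d", feature$id, seq_len(nrow(out)))
  } else {
    out$name <- character(0)
  }
  check_reads(out, "emit_reads")
  out
}

#' Simulate a CRISPR array with structured repeats
#'
#' Lays out `n_repeats` direct repeats separated by spacers; each repeat is
#' assigned a hairpin structure (paired) and spacers are unpaired — the
#' configuration in which only repeats should survive structure-protected
#' digestion. Also emits a minCED-style GFF for the repeats, which
#' round-trips through [parse_crispr_gff()].
#'
#' @param n_repeats number of direct repeats (>= 2).
#' @param repeat_len repeat length in nt (default 30).
#' @param spacer_len spacer length in nt (default 35).
#' @param seed RNG seed for the sequence.
#' @param contig contig name for the array.
#' @param array_start 0-based genomic start of the first repeat.
#' @param gff_path optional path; when given the minCED-style GFF is
#'   written there.
#' @return list with `array` (a `crispr_array`), `structure`
#'   (a [structure_annotation()] over the array span), `feature`
#'   (single-row feature table for the span, `+` strand), `gff_lines`,
#'   and `gff_path` (NULL unless written).
#' @export
simulate_crispr_array <- function(n_repeats, repeat_len = 30,
                                  spacer_len = 35, seed = 1,
                                  contig = "crispr_ctg", array_start = 100,
                                  gff_path = NULL) {
  if (n_repeats < 2) stop("simulate_crispr_array: n_repeats must be >= 2")
  set.seed(seed)
  rand_base <- function(n) sample(names(COMPLEMENT), n, replace = TRUE)
  stem <- (repeat_len - 4L) %/% 2L
  loop <- repeat_len - 2L * stem
  if (stem < 2) stop("simulate_crispr_array: repeat_len too short for a hairpin")
  rep_db <- paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
  rep_seq <- function() {
    left <- rand_base(stem)
    paste(c(left, rand_base(loop), rev(unname(COMPLEMENT[left]))),
          collapse = "")
  }
  unit <- repeat_len + spacer_len
  span_len <- n_repeats * repeat_len + (n_repeats - 1L) * spacer_len
  db <- character(0); sq <- character(0)
  for (k in seq_len(n_repeats)) {
    db <- c(db, rep_db)
    sq <- c(sq, rep_seq())
    if (k < n_repeats) {
      db <- c(db, strrep(".", spacer_len))
      sq <- c(sq, paste(rand_base(spacer_len), collapse = ""))
    }
  }
  array_id <- "CRISPR1"
  structure_ann <- structure_annotation(array_id, paste(sq, collapse = ""),
                                        paste(db, collapse = ""))
  rep_start <- array_start + (seq_len(n_repeats) - 1L) * unit
  repeats <- data.frame(contig = contig, start = as.integer(rep_start),
                        end = as.integer(rep_start + repeat_len),
                        strand = "+", stringsAsFactors = FALSE)
  spacers <- data.frame(contig = contig,
                        start = repeats$end[-n_repeats],
                        end = repeats$start[-1], strand = "+",
                        stringsAsFactors = FALSE)
  array <- crispr_array(array_id, repeats, spacers)
  gff_lines <- c(
    "##gff-version 3",
    sprintf(paste0("%s\tminced:0.2.0\trepeat_region\t%d\t%d\t.\t.\t.\t",
                   "ID=%s;rpt_family=CRISPR;rpt_type=direct"),
            contig, repeats$start + 1L, repeats$end, array_id)
  )
  if (!is.null(gff_path)) writeLines(gff_lines, gff_path)
  feature <- data.frame(id = array_id, contig = contig,
                        start = array$span$start, end = array$span$end,
                        strand = "+", biotype = "other",
                        stringsAsFactors = FALSE)
  list(array = array, structure = structure_ann, feature = feature,
       gff_lines = gff_lines, gff_path = gff_path)
}

#' Simulate ribosome-footprint background reads over an ORF
#'
#' Uniformly placed footprints with lengths uniform in
#' `footprint_len_range` (bacterial ribosome-protected footprints span
#' roughly 15-40 nt), all fully contained in the ORF. This is the coding
#' background against which contaminant signal is distinguished.
#'
#' @param orf single-row feature data.frame (strand `+` or `-`).
#' @param n_footprints number of reads to emit.
#' @param footprint_len_range integer length-2 vector (default `c(15, 40)`).
#' @param seed RNG seed.
#' @param sample_id library label.
#' @return internal alignment table.
#' @export
simulate_riboseq_background <- function(orf, n_footprints,
                                        footprint_len_range = c(15, 40),
                                        seed = 1, sample_id = "sim_bg") {
  check_intervals(orf, "simulate_riboseq_background")
  if (!orf$strand %in% c("+", "-")) {
    stop("simulate_riboseq_background: orf must be stranded")
  }
  L <- orf$end - orf$start
  if (L < footprint_len_range[2]) {
    stop("simulate_riboseq_background: orf shorter than maximum footprint")
  }
  set.seed(seed)
  if (n_footprints == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      query_length = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE))
  }
  len <- sample(seq(footprint_len_range[1], footprint_len_range[2]),
                n_footprints, replace = TRUE)
  start <- orf$start + vapply(len, function(l) {
    sample.int(L - l + 1L, 1L) - 1L
  }, integer(1))
  data.frame(contig = orf$contig, start = as.integer(start),
             end = as.integer(start + len), strand = orf$strand,
             query_length = as.integer(len), sample_id = sample_id,
             stringsAsFactors = FALSE)
}
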