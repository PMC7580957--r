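# Pipeline orchestration: validated run configuration, staged execution
# with TSV outputs and a machine-readable manifest, and the scenario
# simulator that emits a complete synthetic input set.

#' Build a validated pipeline configuration
#'
#' @param alignments path to BED6/SAM/BAM alignments (required for every
#'   stage that consumes reads).
#' @param genome optional FASTA path (enables the ORF-scan stage).
#' @param features optional GFF3 path of annotated features.
#' @param structures optional dot-bracket file (enables the junction stage).
#' @param crispr_gff optional minCED-style GFF (enables the CRISPR stage).
#' @param prodigal_scores optional Prodigal `-s` table.
#' @param out_dir output directory (created if needed).
#' @param rpkm_threshold RPKM cutoff for the expressed call (default 10).
#' @param min_orf_len minimum ORF length in nt (default 15).
#' @param small_orf_aa small-ORF cutoff in aa (default 50).
#' @param max_read_len machine read length; mandatory for end profiling,
#'   no default is inferred.
#' @param tolerance peak/junction distance tolerance in nt for the
#'   per-end-type tests (default 2; the pooled cut-site test uses 0).
#' @param min_count peak-calling floor; `NULL` (default) for the
#'   depth-adaptive floor of [call_peaks()].
#' @param n_perm permutations for the enrichment tests (default 1000).
#' @param seed RNG seed for the permutation nulls (default 17).
#' @param stranded strand-specific read counting for RPKM (default FALSE).
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(alignments, genome = NULL, features = NULL,
                       structures = NULL, crispr_gff = NULL,
                       prodigal_scores = NULL, out_dir = "ribofrag_out",
                       rpkm_threshold = 10, min_orf_len = 15,
                       small_orf_aa = 50, max_read_len = NULL,
                       tolerance = 2, min_count = NULL, n_perm = 1000,
                       seed = 17, stranded = FALSE) {
  for (p in c(alignments, genome, features, structures, crispr_gff,
              prodigal_scores)) {
    if (!is.null(p) && !file.exists(p)) stop("run_config: file not found: ", p)
  }
  if (rpkm_threshold < 0 || min_orf_len < 3 || small_orf_aa < 1 ||
      tolerance < 0 || (!is.null(min_count) && min_count < 1) || n_perm < 1) {
    stop("run_config: threshold out of range")
  }
  if (!is.null(max_read_len) && max_read_len <= 0) {
    stop("run_config: max_read_len must be positive")
  }
  structure(
    list(alignments = alignments, genome = genome, features = features,
         structures = structures, crispr_gff = crispr_gff,
         prodigal_scores = prodigal_scores, out_dir = out_dir,
         rpkm_threshold = rpkm_threshold, min_orf_len = min_orf_len,
         small_orf_aa = small_orf_aa, max_read_len = max_read_len,
         tolerance = tolerance, min_count = min_count, n_perm = n_perm,
         seed = seed, stranded = stranded),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full contaminant-analysis pipeline
#'
#' Executes, in order: RPKM expression calls, ORF-overlap classification,
#' 5'/3' end profiling, junction enrichment, and CRISPR repeat/spacer
#' partitioning — each stage skipped (and noted in the manifest) when its
#' inputs are absent from the configuration. One TSV per stage plus a
#' summary TSV and a JSON manifest of every parameter are written under
#' `config$out_dir`. Outputs are deterministic: identical configuration and
#' seed give byte-identical files.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the per-stage in-memory results, the
#'   summary data.frame, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_run <- character(0)
  report <- list()

  reads <- run_stage("read_alignments", read_alignments(config$alignments))
  features <- if (!is.null(config$features)) {
    run_stage("read_features", read_gff_features(config$features))
  }

  # --- expression ---
  if (!is.null(features) && nrow(features) > 0) {
    expr <- run_stage("rpkm", expression_table(
      reads, features, threshold = config$rpkm_threshold,
      stranded = config$stranded))
    write_tsv(expr, file.path(config$out_dir, "expression.tsv"))
    report$expression <- expr
    stages_run <- c(stages_run, "rpkm")
  }

  # --- ORF overlap ---
  if (!is.null(config$genome) && !is.null(features) &&
      any(features$biotype == "ncRNA")) {
    orf_class <- run_stage("orfscan", {
      ncrnas <- features[features$biotype == "ncRNA", , drop = FALSE]
      orfs <- enumerate_orfs(config$genome, min_len = config$min_orf_len)
      orfs$has_rbs <- find_rbs(config$genome, orfs)
      scores <- if (!is.null(config$prodigal_scores)) {
        read_prodigal_scores(config$prodigal_scores)
      }
      classify_ncrna_overlap(ncrnas, orfs, scores,
                             small_orf_aa = config$small_orf_aa)
    })
    write_tsv(orf_class, file.path(config$out_dir, "orf_overlap.tsv"))
    report$orf_overlap <- orf_class
    stages_run <- c(stages_run, "orfscan")
  }

  # --- end profiles ---
  profiles <- list()
  if (!is.null(features) && !is.null(config$max_read_len)) {
    stranded_feats <- features[features$strand %in% c("+", "-") &
                                 features$biotype == "ncRNA", , drop = FALSE]
    if (nrow(stranded_feats) > 0) {
      profiles <- run_stage("endprofile", {
        parts <- filter_fragment_truncated(reads, config$max_read_len)
        prof_dir <- file.path(config$out_dir, "profiles")
        dir.create(prof_dir, showWarnings = FALSE)
        out <- list()
        for (i in seq_len(nrow(stranded_feats))) {
          feat <- stranded_feats[i, , drop = FALSE]
          prof <- compute_end_profile(parts$kept, feat)
          out[[feat$id]] <- prof
          write_tsv(as.data.frame(prof),
                    file.path(prof_dir, paste0(feat$id, ".tsv")))
          profile_to_tracks(prof, feat, file.path(prof_dir, feat$id))
        }
        out
      })
      report$profiles <- profiles
      stages_run <- c(stages_run, "endprofile")
    }
  }

  # --- junction enrichment ---
  if (!is.null(config$structures) && length(profiles) > 0) {
    junc <- run_stage("junctions", {
      structs <- read_dotbracket(config$structures)
      rows <- list()
      for (sid in intersect(names(structs), names(profiles))) {
        js <- junctions_from_dotbracket(structs[[sid]])
        if (length(js$positions) == 0) next
        pks <- list(
          five_prime = call_peaks(profiles[[sid]], "five_prime",
                                  min_count = config$min_count),
          three_prime = call_peaks(profiles[[sid]], "three_prime",
                                   min_count = config$min_count))
        pks$cut_site <- pool_cut_site_peaks(pks$five_prime, pks$three_prime)
        for (et in names(pks)) {
          pk <- pks[[et]]
          if (length(pk$positions) == 0) next
          tol <- if (et == "cut_site") 0 else config$tolerance
          er <- junction_enrichment(pk, js, tolerance = tol,
                                    n_perm = config$n_perm,
                                    seed = config$seed)
          rows[[length(rows) + 1]] <- data.frame(
            feature_id = sid, end_type = et,
            n_peaks = length(pk$positions),
            n_junctions = length(js$positions),
            tolerance = tol,
            statistic = er$statistic, null_mean = er$null_mean,
            p_value = er$p_value, stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(junc)) {
      write_tsv(junc, file.path(config$out_dir, "junctions.tsv"))
      report$junctions <- junc
      stages_run <- c(stages_run, "junctions")
    }
  }

  # --- CRISPR partitioning ---
  if (!is.null(config$crispr_gff)) {
    crispr <- run_stage("crispr", {
      arrays <- parse_crispr_gff(config$crispr_gff)
      rows <- list()
      for (a in arrays) {
        depth <- depth_over_interval(reads, a$span)
        if (sum(depth) == 0) next
        part <- repeat_spacer_partition(depth, a, n_perm = config$n_perm,
                                        seed = config$seed)
        rows[[length(rows) + 1]] <- data.frame(
          array_id = a$array_id, n_repeats = a$n_repeats,
          repeat_signal_fraction = part$enrichment$statistic,
          repeat_length_fraction = part$repeat_length_fraction,
          p_value = part$enrichment$p_value,
          n_signal_positive = part$n_signal_positive,
          stringsAsFactors = FALSE)
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(crispr)) {
      write_tsv(crispr, file.path(config$out_dir, "crispr.tsv"))
      report$crispr <- crispr
      stages_run <- c(stages_run, "crispr")
    }
  }

  # --- summary + manifest ---
  summary_df <- data.frame(
    metric = c("n_reads",
               "n_features",
               "n_expressed",
               "n_ncrna_no_possible_orf",
               "n_ncrna_orf_with_support",
               "n_arrays_signal"),
    value = c(nrow(reads),
              if (is.null(features)) 0L else nrow(features),
              if (is.null(report$expression)) NA_integer_ else
                sum(report$expression$expressed),
              if (is.null(report$orf_overlap)) NA_integer_ else
                sum(report$orf_overlap$category == "no_possible_orf"),
              if (is.null(report$orf_overlap)) NA_integer_ else
                sum(report$orf_overlap$category == "orf_with_support"),
              if (is.null(report$crispr)) NA_integer_ else
                nrow(report$crispr))
  )
  write_tsv(summary_df, file.path(config$out_dir, "summary.tsv"))
  manifest <- c(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                list(stages_run = stages_run,
                     package_version = as.character(
                       utils::packageVersion("ribofrag"))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$summary <- summary_df
  report$manifest <- manifest
  invisible(report)
}

#' Simulate a complete input scenario
#'
#' Emits, under `out_dir`, every file the pipeline consumes — genome FASTA,
#' features GFF3, dot-bracket structures, alignments as BED6 and SAM, a
#' minCED-style CRISPR GFF — plus ground-truth TSVs (true junctions and
#' per-read truncation flags) sufficient to verify downstream results.
#'
#' Scenarios: `"ssrs-like"` is one structured ncRNA transcript digested
#' under the structure-protection model plus a coding ORF with uniform
#' ribosome-footprint background; `"crispr"` is one CRISPR array with
#' structured repeats and unstructured spacers; `"mixed"` combines both.
#'
#' @param scenario one of `"ssrs-like"`, `"crispr"`, `"mixed"`.
#' @param out_dir output directory.
#' @param seed master RNG seed; per-component seeds are derived from it.
#' @param transcript_length,n_stems geometry of the structured transcript
#'   (defaults 300 nt, 4 stems).
#' @param config a [digestion_config()] governing the digestion; its seed
#'   field is overridden by seeds derived from `seed`.
#' @param n_repeats CRISPR repeats (default 18).
#' @param n_footprints coding-background footprint count (default 1000).
#' @return invisibly, a list with the file paths and the in-memory ground
#'   truth (structures, features, reads with truncation flags, array).
#' @export
simulate_scenario <- function(scenario = c("mixed", "ssrs-like", "crispr"),
                              out_dir, seed = 1,
                              transcript_length = 300, n_stems = 4,
                              config = digestion_config(),
                              n_repeats = 18, n_footprints = 1000) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  want_ssrs <- scenario %in% c("mixed", "ssrs-like")
  want_crispr <- scenario %in% c("mixed", "crispr")

  genome <- list()
  features <- list()
  structures <- list()
  reads <- list()
  truth <- list()
  rand_flank <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }

  if (want_ssrs) {
    st <- simulate_structured_transcript(transcript_length, n_stems,
                                         seed = seed,
                                         feature_id = "ncrna_1")
    set.seed(seed + 1L)
    left <- rand_flank(200)
    right <- rand_flank(200)
    genome$ctg_ncrna <- paste0(left, st$sequence, right)
    features$ncrna <- data.frame(
      id = "ncrna_1", contig = "ctg_ncrna", start = 200L,
      end = 200L + st$length, strand = "+", biotype = "ncRNA",
      stringsAsFactors = FALSE)
    structures$ncrna <- st
    cfg <- config
    cfg$seed <- seed + 2L
    dig <- digest(st, cfg)
    reads$ncrna <- emit_reads(dig$fragments, cfg, features$ncrna,
                              sample_id = "sim_riboseq")
    truth$ncrna <- dig$ground_truth

    # a genuine coding ORF with footprint background on its own contig
    set.seed(seed + 3L)
    n_codons <- 150L
    body <- sample(setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), n_codons, replace = TRUE)
    orf_seq <- paste0("ATG", paste(body, collapse = ""), "TAA")
    genome$ctg_cds <- paste0(rand_flank(100), orf_seq, rand_flank(100))
    features$cds <- data.frame(
      id = "cds_1", contig = "ctg_cds", start = 100L,
      end = 100L + nchar(orf_seq), strand = "+", biotype = "CDS",
      stringsAsFactors = FALSE)
    reads$bg <- simulate_riboseq_background(features$cds, n_footprints,
                                            seed = seed + 4L)
    reads$bg$truncated <- FALSE
    reads$bg$name <- sprintf("bg_%d", seq_len(nrow(reads$bg)))
  }

  crispr_gff_path <- NULL
  if (want_crispr) {
    crispr_gff_path <- file.path(out_dir, "crispr.gff")
    arr <- simulate_crispr_array(n_repeats, seed = seed + 5L,
                                 gff_path = crispr_gff_path)
    set.seed(seed + 6L)
    span_len <- arr$feature$end - arr$feature$start
    genome$crispr_ctg <- paste0(rand_flank(100), arr$structure$sequence,
                                rand_flank(100))
    cfg <- config
    cfg$seed <- seed + 7L
    dig <- digest(arr$structure, cfg)
    reads$crispr <- emit_reads(dig$fragments, cfg, arr$feature,
                               sample_id = "sim_riboseq")
    features$crispr <- arr$feature
    truth$crispr <- dig$ground_truth
    truth$array <- arr$array
    structures$crispr <- arr$structure
  }

  all_reads <- do.call(rbind, lapply(reads, function(r) {
    r[, c("contig", "start", "end", "strand", "query_length", "sample_id",
          "truncated", "name")]
  }))
  rownames(all_reads) <- NULL
  all_features <- do.call(rbind, unname(features))

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    features = file.path(out_dir, "features.gff3"),
    structures = file.path(out_dir, "structures.db"),
    alignments_bed = file.path(out_dir, "alignments.bed"),
    alignments_sam = file.path(out_dir, "alignments.sam"),
    crispr_gff = crispr_gff_path,
    truth_junctions = file.path(out_dir, "ground_truth_junctions.tsv"),
    truth_reads = file.path(out_dir, "ground_truth_reads.tsv")
  )
  gset <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(gset, paths$genome)
  write_gff_features(all_features, paths$features)
  write_dotbracket(structures, paths$structures)
  write_alignments_bed(all_reads, paths$alignments_bed)
  write_alignments_sam(all_reads, setNames(nchar(unlist(genome)),
                                           names(genome)),
                       paths$alignments_sam)
  junc_rows <- do.call(rbind, lapply(structures, function(s) {
    js <- junctions_from_dotbracket(s)
    if (length(js$positions) == 0) return(NULL)
    data.frame(feature_id = s$feature_id, position = js$positions)
  }))
  write_tsv(junc_rows, paths$truth_junctions)
  write_tsv(all_reads[, c("name", "truncated")], paths$truth_reads)

  invisible(list(paths = paths, structures = structures,
                 features = all_features, reads = all_reads,
                 truth = truth, seed = seed))
}
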