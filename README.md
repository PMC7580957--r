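# ribofrag

Fragmentation profiling of structured RNA contaminants in bacterial
Ribo-Seq libraries.

## The problem

Bacterial ribosome profiling (Ribo-Seq) sequences the RNA fragments that
survive micrococcal nuclease (MNase) digestion. Because bacterial
footprints are heterogeneous (15–40 nt), protocols select a broad 15–45 nt
fragment window, and fragments of abundant structured noncoding RNAs
(ncRNAs) — 6S RNA, SRP RNA, CRISPR arrays — persist in the libraries as
contaminants. `ribofrag` is for researchers who want to (a) recognize this
contaminant signal before interpreting Ribo-Seq coverage as translation,
and (b) repurpose it: if base-paired regions resist MNase, the 5′/3′ ends
of contaminant reads mark boundaries between paired and unpaired regions,
turning existing Ribo-Seq data into a crude in-vivo structure probe.

## What it computes

* **Expression** — RPKM per annotated feature with any-overlap counting
  (`bedtools multicov` semantics) and a strict threshold call:
  `rpkm = count / (length/1000) / (total_mapped/1e6)`, expressed iff
  `rpkm > 10`.
* **ORF overlap** — exhaustive six-frame ORF enumeration (starts
  `ATG/GTG/TTG`, stops `TAA/TAG/TGA`, ≥ 15 nt, stop included),
  Shine-Dalgarno detection (`AGGAGG`, ≤ 1 mismatch, 5–13 nt spacer), and
  per-ncRNA classification into `no_possible_orf` / `possible_orf_only` /
  `orf_with_support` (positive Prodigal start or coding score, RBS, or
  < 50 aa), consuming Prodigal `-s` output.
* **End profiles** — strand-aware per-position 5′ and 3′ read-end counts
  over each feature, after removing reads at machine read length (their 3′
  ends are sequencer artifacts, not nuclease cuts).
* **Junction enrichment** — peaks (depth-adaptive floor, leftmost tie
  rule) versus structure junctions from dot-bracket annotations, tested
  with a circular-rotation permutation null:
  `p = (1 + #{null ≥ obs})/(n_perm + 1)`. The headline test pools 5′ and
  3′ peaks on their common cut-bond coordinate and matches junctions
  exactly.
* **CRISPR partitioning** — fraction of signal inside direct repeats
  versus the repeat-length fraction of the array, with per-repeat
  signal-positive calls, from minCED-style GFF annotations.
* **Simulation** — a seeded structure-protected digestion generator
  (per-bond cuts at 0.2 accessible / 0.005 protected, 15–45 nt size
  selection, footprint background, CRISPR arrays) providing ground truth
  for every stage.

See `vignettes/ribofrag-methods.Rmd` for the models, parameter rationale,
and limitations.

## Worked example

```r
library(ribofrag)
sim_dir <- tempfile("sim"); out_dir <- tempfile("out")
sc <- simulate_scenario("mixed", sim_dir, seed = 1)   # genome, GFF3, BED/SAM, structures, CRISPR GFF
rep <- run_pipeline(run_config(
  alignments = sc$paths$alignments_bed,
  genome     = sc$paths$genome,
  features   = sc$paths$features,
  structures = sc$paths$structures,
  crispr_gff = sc$paths$crispr_gff,
  out_dir    = out_dir, max_read_len = 36, seed = 17))
rep$junctions
#>   feature_id    end_type n_peaks n_junctions tolerance statistic  null_mean     p_value
#> 1    ncrna_1  five_prime       9          16         2 0.8888889 0.24088889 0.019980020
#> 2    ncrna_1 three_prime       9          16         2 0.8888889 0.24322222 0.019980020
#> 3    ncrna_1    cut_site      17          16         0 0.7647059 0.05417647 0.003996004
rep$crispr
#>   array_id n_repeats repeat_signal_fraction repeat_length_fraction     p_value n_signal_positive
#> 1  CRISPR1        18              0.7311819              0.4757709 0.000999001                18
```

Reading the output: 76% of pooled cut-site peaks on the simulated
structured ncRNA fall exactly on paired/unpaired junctions, against a
5.4% expectation under random placement (p ≈ 0.004) — read ends
concentrate at structure boundaries. In the 18-repeat CRISPR array, 73% of
the retained signal lies inside direct repeats although they cover only
48% of the span (p ≈ 0.001), and all 18 repeats are individually
signal-positive: spacers were digested, structured repeats survived.

A thin CLI over the same functions is available at `exec/ribofrag`
(`simulate`, `rpkm`, `orfscan`, `endprofile`, `run`).

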