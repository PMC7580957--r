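---
title: "Methods: fragmentation profiling of structured RNA contaminants in bacterial Ribo-Seq"
author: "ribofrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation profiling of structured RNA contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofrag)
```

## The problem

Bacterial ribosome profiling (Ribo-Seq) digests cellular RNA with
micrococcal nuclease (MNase) and sequences the surviving short fragments.
Because bacterial ribosome-protected footprints span a broad 15–40 nt
range, protocols select a wide 15–45 nt fragment window, and monosome
enrichment is imperfect. Fragments of abundant noncoding RNAs (ncRNAs)
therefore persist in the libraries as contaminants. The working hypothesis
this package operationalizes is that these contaminants survive because
base-paired (stem) regions are sterically protected from MNase, while
accessible single-stranded regions are cut. Two testable consequences
follow:

1. the 5′ and 3′ ends of contaminant reads should accumulate at
   *junctions* between paired and unpaired regions of a structured ncRNA;
2. in CRISPR arrays — where direct repeats fold into hairpins and spacers
   are unstructured — retained signal should concentrate in the repeats.

The package quantifies ncRNA signal (RPKM), rules out coding explanations
(exhaustive ORF enumeration with ribosome-binding-site detection and
Prodigal score support), builds strand-aware 5′/3′ read-end profiles, and
tests both consequences with circular-permutation tests. A seeded
digestion simulator provides ground truth for every stage.

## Coordinate conventions

All internal coordinates are 0-based, half-open `[start, end)` with strand
in `{+, -, .}`. GFF3 and SAM (1-based inclusive) are converted at the file
boundary; BED and bedGraph pass through unchanged. For a read on the `+`
strand spanning `[s, e)`, the 5′ end is `s` and the 3′ end is `e − 1`; on
the `-` strand the roles swap. Profiles are reported feature-relative,
oriented 5′→3′ along the feature's strand, so minus-strand features read
like their transcripts. Reads without strand (`.`) are accepted for
coverage/RPKM but never contribute to end profiles, since end assignment
requires orientation.

## Expression (RPKM)

`rpkm = count / (length/1000) / (total_mapped/1e6)`, with any-overlap
(≥ 1 nt) strand-agnostic counting — the default behavior of
`bedtools multicov` — and the library's total primary mapped alignments as
the denominator. The expression call is strict: a feature at exactly the
threshold (default 10) is *not* called expressed. No deduplication is
applied anywhere.

## ORF overlap classification

All possible ORFs are enumerated on both strands and all three frames:
start codons `{ATG, GTG, TTG}` to the nearest in-frame stop
`{TAA, TAG, TGA}`, stop included in the length, minimum 15 nt (≥ 4 aa +
stop — the bacterial gene-caller convention). Nested starts sharing a stop
are distinct candidates. A ribosome-binding (Shine–Dalgarno) site is
called when `AGGAGG` matches within ≤ 1 mismatch at a 5–13 nt spacer
upstream of the start codon, strand-aware; all three parameters are
configurable because no standard detector is implied by the analysis.
Each ncRNA is then classified against the ORFs overlapping it by ≥ 1 nt on
either strand:

* `no_possible_orf` — no overlapping ORF at all;
* `orf_with_support` — some overlapping ORF has a positive Prodigal start
  score, positive coding score, a detected RBS, or is small (< 50 aa);
* `possible_orf_only` — otherwise.

Prodigal's own model is consumed, not re-implemented: its `-s`
intermediate table is parsed and joined to the enumerated ORFs by exact
coordinates.

## End profiles and the fragment-length filter

Only reads fully contained in a feature contribute to its profile by
default (`partial = TRUE` relaxes this): boundary-straddling reads would
attribute end positions belonging to neighboring loci. Before profiling,
reads with `query_length >= max_read_len` are removed — a read at machine
read length cannot certify that its fragment ended where the read does, so
its 3′ end is a sequencer artifact rather than a nuclease cut. The
boundary is deliberately inclusive, and `max_read_len` is mandatory input:
read lengths differ between libraries and are not inferred.

## Peak calling

Position `i` is a peak when `count[i]` reaches a floor, strictly exceeds
every count in the `window` (default 2) positions to its left, and is at
least every count to its right — the asymmetric rule makes tied runs
resolve to their leftmost position deterministically.

The default floor is depth-adaptive: `max(5, ceiling(2 × mean count))`.
The rationale is arithmetic: a profile with `N` reads over `L` positions
has mean end density `N/L`, and any fixed absolute floor is exceeded by
background alone once `N/L` approaches it (at 2,000 reads over 300 nt the
mean is 6.7 per position). A floor of twice the mean keeps background
(approximately Poisson) positions below threshold at any depth while
junction-driven peaks, which concentrate an order of magnitude more mass,
clear it comfortably. A fixed `min_count` can always be supplied
explicitly.

## The junction test

A junction is a position whose paired state differs from its
predecessor's (0-based, in `[1, L−1]`). The association statistic is the
fraction of peaks within `tolerance` nt (circular distance) of any
junction. The null distribution rotates all peak positions together by a
uniform random offset — a stricter null than uniform resampling because it
preserves the peaks' spacing structure — and
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, so `p` has floor
`1/(n_perm+1)` and ceiling 1.

Two refinements matter at realistic depth:

* **Cut-site pooling.** A cut at bond `b` (between positions `b−1` and
  `b`) produces a 3′ end at `b−1` and a 5′ end at `b`: both end types
  estimate the same cut. `pool_cut_site_peaks()` merges the two peak sets
  on the bond coordinate (3′ position + 1), and junction positions are
  bond positions by construction. The pooled test
  (`profile_junction_test()`) therefore uses tolerance 0 by default.
* **Why a small tolerance is not conservative but necessary.** With a
  circular-shift null, every offset at which the shifted configuration
  ties the observed statistic contributes to the p-value. If peaks match
  junctions with slack `t`, all `2t+1` offsets in `[−t, t]` tie, so the
  p-value cannot fall below `(2t+1)/L` regardless of how strong the
  association is — for `t = 2` and `L = 300` that is 0.017. Pooling to
  exact bond coordinates removes the slack and restores the `1/L` floor.

Per-end-type tests at the conventional tolerance of 2 nt remain available
(`junction_enrichment()`) and are reported alongside the pooled test by
the pipeline. Junction *recovery* — the fraction of true junctions with a
called peak of either end type within ±2 nt — is reported separately as a
sensitivity measure.

## CRISPR repeat/spacer partitioning

minCED-style GFFs carry repeats only; spacers are derived as the gaps
between consecutive repeats. The statistic is the fraction of total depth
falling inside repeats; under uniform coverage it equals the repeat-length
fraction of the array span exactly. The null rotates the depth vector
circularly. Each repeat is flagged signal-positive when its mean depth
reaches 1 (configurable): with ~47% of a default array inside repeats and
thousands of fragments, this is a low bar for genuine protection and a
fair bar for spacers.

## The digestion simulator

`digest()` implements the protection model directly: for each molecule
copy, every inter-nucleotide bond is cut independently with probability
`p_cut_paired` (default 0.005) when **both** flanking bases are paired,
else `p_cut_unpaired` (default 0.2). Placing cuts on bonds makes
junction-adjacent bonds (one paired, one unpaired flank) accessible —
exactly the mechanism that piles read ends onto junctions. Fragments are
the runs between cuts (molecule ends count as cuts); a hard 15–45 nt size
window models the protocol's gel selection with no length-efficiency
curve. Each fragment becomes one error-free ungapped read; fragments at or
above the machine read length (36 nt default) are truncated from the 5′
end and flagged — the ground truth for the fragment-length filter.
Sequence-specific nuclease preference, ligation bias, and mapping error
are deliberately out of scope, so passing tests demonstrate the
statistical machinery, not robustness to those real-data artifacts.

Transcript geometry defaults were chosen once, on mechanistic grounds:

* **Hairpin size inside the selection window.** Stems of 14–17 bp with
  3-nt loops give 31–37 nt hairpins; a protected fragment must fit the
  15–45 nt window to be observed at all.
* **Stems at least 14 bp.** A surviving fragment starting at a stem
  boundary must reach ≥ 15 nt before its next accessible bond. With stem
  `s` and loop 3, the mode of surviving 5′ ends sits at
  `stem_start − (14 − s)`: for `s < 14` the size floor displaces peaks
  off the junction, for `s ≥ 14` they sit on it.
* **Mixed stem lengths.** Identical hairpins make the internal junction
  spacings periodic, so circular rotations that map one hairpin onto
  another inflate the null; sampling stems from 14–17 breaks the
  degeneracy.
* **600 molecules** yield roughly 2,500–4,000 size-selected fragments for
  a 300-nt, 4-stem transcript — enough depth for stable peaks while
  keeping every simulation-based check fast.
* Linkers get a minimum of 3 nt plus a random allocation of the
  remainder, so junction positions vary across seeds.

The true in-vivo protection ratio is unknown; these defaults make
recovery achievable at desk scale and are not claimed to be biologically
calibrated.

## Calibration

With protection switched off (`p_cut_paired = p_cut_unpaired`) the
fragmentation field is independent of the structure, so junction-test
p-values must be uniform. The calibration experiment verifies this over
100 seeded simulations (fresh random structure per seed) with a
Kolmogorov–Smirnov check and the empirical type-I error at nominal 0.05.
It uses the per-end test at tolerance 2 with the fixed floor of 5: that
configuration yields dense peak sets and a near-continuous p-value
distribution, a precondition for a meaningful uniformity check (the
pooled tolerance-0 statistic on sparse peak sets is so discrete under the
null — typically 0 — that most p-values are exactly 1).

## Worked example

```{r example, eval = FALSE}
sim_dir <- tempfile("sim"); out_dir <- tempfile("out")
sc <- simulate_scenario("mixed", sim_dir, seed = 1)
rep <- run_pipeline(run_config(
  alignments = sc$paths$alignments_bed,
  genome = sc$paths$genome,
  features = sc$paths$features,
  structures = sc$paths$structures,
  crispr_gff = sc$paths$crispr_gff,
  out_dir = out_dir, max_read_len = 36, seed = 17))
rep$junctions   # per-end and pooled cut-site junction tests
rep$crispr      # repeat/spacer partition for the 18-repeat array
```

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one estimator; they are never 0.
* Peak ties resolve leftmost; all outputs are deterministic for a fixed
  seed, and every stochastic routine draws from one seeded generator per
  invocation.
* Zero peaks is an error ("no peaks to test"), distinct from a negative
  result; zero total depth over a CRISPR array likewise.
* Unbalanced dot-bracket strings, length-mismatched structures, duplicate
  feature IDs, overlapping repeats, and non-nucleotide genome characters
  (other than `N`) are rejected at parse time; ORFs containing `N` are
  skipped and counted.
* Gapped alignments are represented by their reference span; bacterial
  Ribo-Seq alignments are effectively ungapped.

## Problem sizes

The shipped checks run at: 300-nt transcripts with 4 hairpins and 600
digested molecules (≈ 3,900 selected fragments), 10 replicate seeds for
recovery, 100 replicate seeds for calibration, an 18-repeat CRISPR array
(1,135 nt span), and 1,000–2,000 permutations per test. A full test run
completes in well under a minute of CPU.

## Known limitations

* The junction statistic weighs peaks, not their heights; a peak-height
  weighted variant would be more powerful but less interpretable.
* The simulator's uniform per-bond cut model omits MNase's A/T sequence
  preference; observed peak heights on real data will be modulated by it.
* Absence of a peak does not imply absence of structure: size selection
  censors fragments outside 15–45 nt, and monosome enrichment upstream of
  sequencing removes contaminants nonuniformly.
* Real structures contain internal loops, bulges and multi-branch
  junctions; the simulator emits only terminal-loop hairpins, which is
  sufficient for the paired/unpaired junction logic the tests exercise.
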