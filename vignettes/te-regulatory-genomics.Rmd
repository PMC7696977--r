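---
title: "Repeat-aware regulatory genomics with retroreg: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware regulatory genomics with retroreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

retroreg implements a pipeline for studying the regulatory activity of
transposable-element (TE) loci — in particular young LTR retrotransposon
families such as the human-specific LTR5_Hs of HERV-K — from the standard
inputs of a regulatory-genomics study: repeat annotation, gene models, read
alignments, signal tracks, peak calls, genome sequence, and
differential-expression tables. This vignette explains the models behind
each stage, the parameters that matter, what the synthetic-data generators
do and do not emulate, and the numerical and design choices made where the
methodology left room.

## Coordinates and locus filtering

Every coordinate inside the package is 0-based and half-open (BED
convention); GTF (1-based inclusive) and SAM (1-based) are converted at I/O
only. A TE locus is removed before quantification if it overlaps any exon
or UTR by at least one base, or if its nearest base lies within
`tss_exclusion_bp` (default 1000 bp) of any transcription start site. The
boundary is *inclusive* — a locus exactly 1 kb from a TSS is removed. The
inclusive reading is a choice: the exclusion is a guard against promoter
bleed-through, so borderline loci are treated conservatively, and the
boundary is pinned by tests in both directions. The TSS is the 5′-most exon
boundary on the gene's strand; isoform-level TSS variation is out of scope.

## Family-level expression: the exclusive-family rule

Reads from recently expanded repeat families map to many near-identical
loci. At the family level ambiguity is resolvable without any model: a read
is informative if *every* reported alignment falls within loci of one and
the same family, in which case it contributes exactly one count to that
family, regardless of its number of alignments. Reads touching two
families, or with any alignment outside annotated TE loci, are discarded.
An alignment counts as "within" a locus when at least `read_overlap_frac`
(default 50%) of the read lies inside it; the methodology leaves this
undefined and 50% mirrors the peak-intersection convention used elsewhere
in the pipeline.

Counts are normalized as CPM = count × 10⁶ / `total_mappable_reads`, where
the denominator is the number of reads mappable anywhere on the genome.
That denominator cannot be recovered from a TE-restricted alignment stream,
so it is an explicit argument everywhere and never inferred. Expression is
compared as log₂(CPM + 1).

## Locus-level expression: EM redistribution

At the locus level ambiguity needs a model. Let L(r) be the candidate locus
set of read r (the loci its alignments fall within) and θ the locus
abundance vector. The E-step assigns r fractionally,
responsibility(l | r) = θ_l / Σ_{k∈L(r)} θ_k; the M-step sets
θ_l ∝ unique_l + Σ_r responsibilities. Iteration stops when
max |Δθ| < `tol` (default 1e-8) or after `max_iter` (default 1000, with
`converged = FALSE` and a warning). Numerical choices:

- **Initialization is uniform**, not proportional to unique counts, so loci
  with zero unique evidence are not zeroed at the start; unique reads still
  dominate the fixed point (for two loci the closed form is
  a = u_A + m·a/(a+b), which the tests verify to 1e-6 for random inputs).
- **Degenerate reads** whose candidates all have θ = 0 receive equal
  fractional shares.
- **No length normalization**: the estimated quantity is a read count
  (reported downstream as CPM), not a density, and candidate loci of one
  family have similar lengths.
- The observed-data log-likelihood Σ_r log Σ_{l∈L(r)} θ_l is recorded per
  iteration and is non-decreasing (a property test).
- Reads are collapsed by candidate-set signature before iterating, so EM
  cost scales with the number of distinct ambiguity patterns, not reads.

MAPQ is deliberately ignored in quantification — multi-mappers have low
MAPQ by construction, and removing them would remove the signal. MAPQ
filtering belongs to the upstream processing of signal/peak inputs.

## Metaprofiles

For each locus, a ±`flank_bp` (default 5000) window around its anchor is
divided into `bin_bp` (default 100) bins. The anchor is the strand-aware 5′
boundary — left edge for `+`, right edge for `−` loci — and bin order is
reversed for `−` loci so that bin 1 is always 5′-most upstream. (The
alternative "literal left boundary" anchor is available via
`anchor = "left"`; the strand-aware form is the default because LTR
regulatory architecture is oriented.) Segment mass is distributed by exact
base-pair overlap (value × overlapping bp), so results are independent of
the track's segment resolution; a midpoint assignment would not be. Bins
are normalized to CPM (mass × 10⁶ / library size). Windows truncated at
chromosome edges contribute zeros, and loci on chromosomes absent from a
track are kept as all-zero rows, so aggregated profiles remain comparable
across tracks. Aggregation over loci is the per-bin mean (a sum is
available via `aggregate = "sum"`); the mean is invariant to the number of
loci and therefore comparable across families of different sizes.

## Peak–family enrichment

Peaks are first merged when separated by strictly less than 50 bp, then
assigned to the single TE locus they overlap most, provided the overlap
covers at least `min_frac` (default 50%) *of the peak*. The fraction is
computed on the peak because the peak is the query being classified
(mirroring `intersectBed -f` semantics); ties are broken by smaller locus
start, then lexicographic locus id, making assignment deterministic and
order-invariant (tested bit-for-bit).

The null expectation for family f is its share of the assigned peaks,
proportional either to the family's total genomic span (`model = "span"`,
the default: peaks are extended objects landing on base pairs) or to its
locus count (`model = "count"`). Both models are implemented because the
notion of "expected ratio" is genuinely open; the choice is a required,
recorded parameter. Each family is then tested with a 1-df two-cell
goodness-of-fit chi-square — (in-family vs out-of-family) × (observed vs
expected) — without continuity correction, upper-tail p, BH adjustment
across families. Families whose expected cell is below 5 are flagged
`low_expected` but still computed. Reporting requires at least
`min_peaks = 5` observed peaks (boundary inclusive). Unassigned peaks are
excluded from the test denominator: the question is how assigned peaks
distribute over families, not how many peaks hit TEs at all.

Calibration is a tested property: with peaks placed uniformly over TE base
pairs, per-family p-values are uniform (the p < 0.05 rate over 200
replicates stays inside the 95% binomial band), and a 3× planted rate on
one family of 50 loci among 400 peaks is detected at p < 0.01 with the
smallest p in ≥ 90% of replicates.

## E-box scanning and the bound/unbound contrast

The scanner finds CACGTG and CATGTG on both strands. CACGTG is its own
reverse complement, so a palindromic match is reported once per position
(strand `+`); a reverse-strand CATGTG appears on the forward sequence as
CACATG. `N` never matches. The implementation (Biostrings pattern
matching) is checked against a brute-force all-6-mers oracle on random
10-kb sequences.

Presence is binary per sequence (≥ 1 hit anywhere), and bound vs unbound
groups are compared with a 2×2 chi-square without continuity correction.
Presence testing operates on *fixed-width* sequences: 51-bp windows, either
summit-centered for peaks (`summit_windows`, summit ± 25 bp inclusive of
the summit base; peak midpoint when no summit is recorded) or
locus-center windows (`locus_center_windows`). The window form matters: in
background sequence a ~650-bp locus already contains an E-box with ~38%
probability purely by chance, so whole-locus presence is confounded by
locus length; equal-width windows keep the background rate low (~3%) and
make the contrast interpretable. Whole-locus scanning remains available
through `extract_sequences` on loci for users who want the locus-level
denominator.

## Expression statistics and integration

- `bh_adjust` is the standard Benjamini–Hochberg step-up (delegating to
  `p.adjust`), tested against a hand-written step-up on random vectors.
- `deg_filter` keeps genes with adjusted p < α (strict) and
  |log₂FC| ≥ `min_abs_lfc` (inclusive by default — the threshold names the
  smallest effect still accepted; a strict variant is a flag).
- `set_overlap_test` requires an explicit universe. There is no defensible
  silent default for "testable genes", and the overlap p-value is highly
  sensitive to it, so omission is a hard error rather than a guess.
- `spearman_corr` is the Pearson correlation of mid-ranks with the
  asymptotic t approximation p-value, matching `cor.test(...,
  method = "spearman", exact = FALSE)` to numerical precision.
- `enhancer_candidates` intersects three criteria — reciprocal response in
  the state contrast (direction set by `reciprocal_sign`), upregulation
  under treatment, and a factor-bound target-family locus within
  `neighborhood_bp = 10000` of the TSS, inclusive (edge-to-TSS distance;
  a locus covering the TSS is at distance 0).
- `ddct_fold_change` averages replicate CTs first, then computes
  2^(−ΔΔCT); one CT cycle is one doubling.

## The synthetic-data module

The generators are pure functions of (parameters, seed) — seeding is
scoped with `withr::with_seed`, so the global RNG stream is untouched —
and their defaults define the study conditions used throughout the tests:

- `make_annotation`: 3 chromosomes × 1 Mb, 4 families × 50 loci of
  300–1000 bp (solo-LTR-sized), 100 genes of 2–8 kb with 2–4 exons. Loci
  are mutually disjoint, as are genes, but loci may fall inside genes by
  chance — that is what the filtering stage is for. Family and within-family
  locus proportions are drawn from a normalized Gamma(5) (moderately uneven,
  as TE family expression is), the planted peak enrichment is 3× on the
  LTR5_Hs-like family, the signal bump has height 1 and sd 200 bp at
  5′ anchors, motif presence probabilities are 0.5 (bound) vs 0.1
  (unbound), and half the target loci are marked bound.
- `simulate_alignments`: 50,000 reads of 100 bp, 40% multi-mapped at 1–3
  extra positions, 10% of extras crossing families (such reads are
  correctly unassignable at the family level).
- `simulate_track` lays bumps down at 1-bp resolution over ±4 sd, so the
  discrete bump mass matches the analytic Gaussian integral within 1%.
- `simulate_de_table`: null genes p ~ U(0,1), log₂FC ~ N(0, 0.2); 100
  planted true genes among 1000 with p ~ Beta(0.01, 1) and |log₂FC| = 2.
- `simulate_de_pair` plants candidate genes eligible by annotation
  geometry plus near-miss decoys that each fail exactly one criterion, so
  the enhancer caller must return exactly the planted set.

What the generators do **not** emulate: sequencing error, fragment-length
and GC biases, locus sequence divergence (reads are placed by coordinates,
not aligned from sequence), copy-number/assembly artifacts, overdispersed
DE null distributions, and correlated replicate structure. Passing tests
therefore demonstrate the correctness and calibration of the computations
under a clean generative model — not robustness to the full messiness of
real libraries, which belongs to upstream alignment and peak-calling
tools that are out of scope here.

Workflow-level fixtures use sparser peak sets (~120 peaks over ~200 loci)
than the module-level power condition (400 peaks over 200 loci): after the
faithful < 50 bp merge step, dense peak sets collapse to one merged peak
per locus and saturate every bound/unbound split, which is realistic but
uninformative for end-to-end checks.

## Workflows, determinism, problem sizes

The three workflow drivers (`run_expression_workflow`,
`run_regulatory_workflow`, `run_integration_workflow`) orchestrate the
stages over files, echo their configuration verbatim into the output
directory, and write a manifest with input/output MD5 checksums, parameter
block, seed and stage timings. Two runs with the same config and seed
produce byte-identical outputs (a tested property). Unknown config keys are
rejected; missing inputs fail before any computation.

Test and acceptance problem sizes were chosen to make every statistical
property measurable with comfortable margins while keeping a full run of
the suite in the low minutes: 1,000-read oracle comparisons, 50,000-read /
10-locus EM recovery (observed max error ≈ 0.002–0.004 against the 0.02
criterion), 200 + 100 enrichment replicates, 100 random 10-kb scanner
sequences, 100-replicate FDR simulations.

## Known limitations

- Paired-end fragments are not modeled; an alignment record is a read.
- The EM assumes candidate sets are generated symmetrically across their
  loci; strong mappability asymmetries would bias it.
- Gene models keep a single TSS (5′-most exon boundary) per gene.
- Chi-square p-values are asymptotic; very small expected cells are
  flagged (`low_expected`) rather than switched to exact tests, except
  where the Fisher test is explicitly requested.
- Genome-build liftover, GFF3 input, peak calling, DE model fitting and
  de-novo motif discovery are out of scope; the package consumes their
  outputs.
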