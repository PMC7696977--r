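# retroreg

Transposable-element-centric regulatory genomics in R: expression
quantification of TE families and loci from multi-mapped alignments, binned
signal metaprofiles over LTR loci, peak–family enrichment statistics, E-box
motif testing, differential-expression thresholding with gene-set overlap
statistics, and LTR-neighborhood enhancer-candidate screening — all of it
exercisable end to end on seeded synthetic data with planted ground truth.

## The problem

Endogenous retroviruses such as HERV-K (HML2) leave hundreds of near-identical
copies in the genome — solo LTRs (LTR5_Hs) and truncated proviruses — which
makes them invisible to standard uniquely-mapping RNA-seq/ChIP-seq pipelines
and, at the same time, interesting: their LTRs carry transcription-factor
binding sites (e.g. the E-box CA(C/T)GTG bound by MITF-class factors) and can
act as enhancers for neighboring genes. Analyzing them requires a consistent
set of repeat-aware methods:

- **Locus filtering.** TE loci overlapping exons/UTRs by ≥ 1 bp, or within
  1 kb of a TSS (inclusive), are removed before quantification so TE signal
  is not confounded by gene transcription.
- **Family expression.** A multi-mapping read is counted only if *every* one
  of its alignments falls within loci of a single repeat family ("exclusive
  family" rule), contributing exactly one count; family expression is
  CPM = count × 10⁶ / (total genome-mappable reads), reported as
  log₂(CPM + 1).
- **Locus expression.** Multi-mapped reads are redistributed across candidate
  loci by expectation–maximization: with locus abundances θ, read *r* gives
  locus *l* responsibility θ_l / Σ_{k∈L(r)} θ_k, and the M-step sets θ ∝
  unique counts + fractional assignments, so uniquely mapped reads anchor the
  fixed point. For two loci with unique counts u_A, u_B and m shared reads
  the fixed point is the closed form a = u_A + m·a/(a+b).
- **Metaprofiles.** Signal tracks are accumulated in 100-bp bins over
  ±5 kb windows anchored at each locus's strand-aware 5′ boundary (bins
  reversed for − strand loci), normalized to CPM per bin, averaged over loci
  and replicates.
- **Peak enrichment.** Peaks merged at < 50 bp gaps are assigned to the TE
  locus they overlap most (≥ 50% of the peak); each family's observed peak
  count is tested against its genomic-span (or locus-count) expectation with
  a 1-df two-cell chi-square, BH-adjusted, reporting families with ≥ 5 peaks.
- **Motif testing.** The E-box CA(C/T)GTG is scanned on both strands
  (palindromic CACGTG counted once per position); presence in bound vs
  unbound loci is compared with a 2×2 chi-square over fixed 51-bp windows.
- **Integration.** DEGs are genes with BH-adjusted p < 0.05 and
  |log₂FC| ≥ 1; gene-set overlaps are tested by chi-square or two-sided
  Fisher over an explicitly supplied universe; enhancer candidates are genes
  that (i) respond reciprocally across the state contrast, (ii) are
  upregulated under treatment, and (iii) have a factor-bound target-family
  locus within 10 kb of the TSS (inclusive). qPCR fold changes use 2^(−ΔΔCT).

Every generator in the synthetic-data module is a pure function of
(parameters, seed) and writes the exact dialects the readers consume (BED6,
GTF, SAM, bedGraph, narrowPeak, FASTA, TSV), so parameter recovery and
calibration are testable end to end.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic data
(01 generates inputs under `results/data/`, 02–06 analyze them):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_peak_enrichment.R
```

prints, for a 120-peak simulation with a 3× planted rate on the LTR5_Hs-like
family:

```
120 peaks merge into 89 (<50 bp gap rule)
89 of 89 merged peaks assigned to a TE locus
   family observed expected  chi2        p     padj low_expected reported
1   L1PA2       19     21.3  0.33 5.66e-01 5.66e-01        FALSE     TRUE
2   LTR13       12     21.3  5.34 2.09e-02 4.17e-02        FALSE     TRUE
3 LTR5_Hs       42     21.9 24.39 7.86e-07 3.15e-06        FALSE     TRUE
4  MER41B       16     24.5  4.04 4.45e-02 5.93e-02        FALSE     TRUE
most significant family: LTR5_Hs (planted enrichment: LTR5_Hs)
```

`observed` is the number of merged peaks assigned to each family, `expected`
its genomic-span share of all assigned peaks; the planted family is the only
one enriched *above* expectation (42 vs 21.9, p ≈ 8×10⁻⁷) — the other
families' small p-values reflect the complementary depletion. Likewise
`analysis/02_te_expression.R` recovers the planted family abundances
(max share error 0.013 after locus filtering) and
`analysis/06_integration.R` returns exactly the planted enhancer-candidate
genes.

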