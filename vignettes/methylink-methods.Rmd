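---
title: "Methods: integrating WGBS methylation with gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating WGBS methylation with gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylink)
```

# Scope and data model

`methylink` integrates two genome-wide read-outs from the same
individuals: CpG methylation from whole-genome bisulfite sequencing
(WGBS) and gene expression from RNA-seq. The motivating setting is a
two-group comparison (e.g. large versus small fish from one rearing
experiment) with a known nuisance factor (feed type / rearing pen), at
modest sequencing depth (~5X) and small sample size (5-10 per group) —
conditions under which single-CpG tests are underpowered and region-level
analysis with permutation calibration is the field's standard answer.

Methylation enters as Bismark-style per-cytosine counts. CpG methylation
is symmetric across strands, so calls on the minus strand are re-anchored
to the plus-strand cytosine of the dinucleotide and summed
(`merge_strands()`); all downstream coordinates are 0-based half-open.
The central container is a loci-by-samples pair of count matrices
(methylated, total); methylation level is always the count-weighted ratio
`sum(meth)/sum(total)`, never a mean of per-CpG ratios, so deeply covered
CpGs carry proportionally more weight, matching how sequencing-level
summaries (e.g. a Bismark report) are computed.

# Global patterns

**Tiling.** The genome is split into fixed 10 kb windows; a window is
kept if it holds at least 100 CpGs and its mean per-CpG coverage across
samples lies in [1X, 30X]. The CpG floor stabilizes tile levels; the
coverage ceiling removes low-complexity pile-ups. Where exactly the
coverage bounds apply (per CpG, per tile, per sample) is a genuinely open
choice; we apply them to the tile mean over CpGs and samples, the
interpretation used by tile-based WGBS toolkits.

**PCA and PERMANOVA.** Sample-level structure is assessed by PCA of
centered (not scaled) tile levels; tiles with any undefined level are
dropped. Group effects are tested with PERMANOVA on Euclidean distances
between tile profiles: pseudo-F from the distance decomposition,
R² = SS_between/SS_total, and a permutation p-value
`(1 + #{F_perm >= F_obs}) / (1 + N)`. When the number of distinct
relabelings (excluding the observed one) is within the permutation
budget, they are enumerated exhaustively; otherwise labels are shuffled
with a seeded stream. The distance metric is configurable; Euclidean is
the default because tile levels are already on a common [0, 1] scale.

**TSS metaprofile.** Mean methylation is profiled in 50 bp bins from
6 kb upstream to 5 kb downstream of every gene's TSS. Offsets are
strand-aware; on the minus strand the offset of genomic position *p* is
`tss - p - 1`, which makes profiles exactly mirror-symmetric under strand
flip. CpGs are pooled across genes and samples with count weighting; a
CpG near two TSSs contributes once per gene. Genes are deliberately not
equally weighted — the profile describes the pooled CpG population.

# DMR detection

The caller tests for differentially methylated regions between the two
groups while adjusting for a stratifying covariate, with a fully
specified smoothing + label-permutation procedure:

1. **Per-CpG difference.** On the complete-coverage matrix (CpGs with
   coverage in every sample — low-coverage sites otherwise dominate the
   noise), the raw difference *d* at each CpG is the reference-group mean
   level minus the other group's, computed within each stratum and
   combined across strata weighted by stratum size. Strata containing
   only one group are excluded with a warning.
2. **Smoothing.** *d* is smoothed by a running mean over CpGs within
   ±500 bp on the same contig. The bandwidth is an exposed assumption
   (not a literature-fixed value): ±500 bp spans ~20 CpGs at typical CpG
   densities, enough to suppress single-CpG noise at 5X without erasing
   sub-kilobase regions.
3. **Regions.** Candidate regions are maximal runs of consecutive CpGs
   with |smoothed d| at or above the cutoff (default 0.05), constant
   sign, inter-CpG gaps at most 1 kb, and at least 5 CpGs. The cutoff
   comparison tolerates float error at 1e-9 so summation order cannot
   flip a boundary CpG. Reported bounds span first to last CpG plus the
   dinucleotide.
4. **Statistic.** Each region gets the signed, variance-standardized sum
   `stat = sum_i d_i / sqrt(s_i^2 + 0.01)` with `s_i^2` the pooled
   within-group between-sample variance at CpG *i*. The additive form
   rewards both effect size and region length; the 0.01 floor stops
   near-zero-variance sites from dominating.
5. **Permutation null.** Group labels are shuffled *within strata* (the
   simplest exchangeability-preserving treatment of the covariate), the
   entire pipeline re-run per relabeling, and all resulting region
   statistics pooled into one null set. The p-value of an observed
   region is `(1 + #{|null| >= |obs|}) / (1 + N_null)`. With 5v5 samples
   in two strata there are only 119 distinct relabelings, so the null is
   enumerated exhaustively; pooling across regions is what gives usable
   resolution at that count. Regions with p < 0.01 are flagged
   candidates, and p-values are deliberately *not* adjusted for multiple
   testing — the design goal is a candidate set for downstream
   feature-level summaries, not individually confirmed loci, and raw
   p < 0.01 with a 5-CpG floor and complete-coverage filtering keeps the
   candidate set usable at small n.

Delta beta (the raw mean difference over the region, reference minus
other) determines direction: hypermethylated in the reference group if
positive. One caveat of pooled nulls is worth knowing: when a large
fraction of all tested regions carries true signal, permuted relabelings
partially reconstruct that signal and the null acquires a heavy tail, so
p-values become conservative. At realistic signal sparsity (a percent or
less of tested regions) the effect is negligible.

# Genomic features and annotation

Five strand-aware intervals are built per gene from its GFF3 record:
proximal promoter P1 (1 kb immediately upstream of the TSS), distal
promoter P6 (upstream of P1 out to 6 kb), gene start GS (first 1.5 kb of
the gene, or the whole gene when shorter — such genes have no gene body),
gene body GB (remainder to the TTS) and TTR (1 kb downstream of the TTS).
The TSS is the strand-aware 5' terminus of the *gene* record; transcript
isoforms are out of scope. P6 excluding P1 is the default because the
implied denominator of the published density table (140/5000 = 0.028) is
the 5 kb distal window, not 6 kb; the flag `p6_excludes_p1 = FALSE`
restores the overlapping construction.

Candidate DMRs are intersected with feature intervals (1 bp minimum
overlap, the `bedtools intersect` convention). Bookkeeping is deliberately
double: `N_A` counts every (DMR, gene, feature) interaction, while
`N_DMRs` assigns each DMR to exactly one class by the hierarchy
P1 > GS > P6 > GB > TTR > Intergenic. The hierarchy is applied *across*
genes (a DMR in gene A's body and gene B's proximal promoter counts as
P1) because it is defined over feature classes, not genes. DMR density
divides `N_DMRs` by the canonical class length: the geometry spans for
P1/GS/TTR, the 5 kb effective window for P6, and the mean gene-body
length over genes longer than 1.5 kb for GB.

# Expression and integration

Counts are filtered by a total-count floor and a prevalence rule (>= 10
reads in >= 50% of samples), normalized by median-of-ratios size
factors. Factors are rescaled to geometric mean exactly 1 — a constant
rescaling that fixes the normalized scale without touching ratios.
Differential expression uses a per-gene linear model of
`log2(normalized + 1)` on group plus stratum indicators with a two-sided
t-test and Benjamini-Hochberg adjustment. This is supporting
infrastructure, not the headline method; negative-binomial shrinkage
machinery is intentionally out of scope, and `log2(x + 1)` is chosen for
zero safety. Genes whose residual variance is at rounding-noise scale
report `lfc = 0, p = 1`.

For every (DMR, gene) pair with an annotation and expression data, the
pair's mean methylation per sample (count-weighted over the DMR's CpGs)
is correlated with the gene's normalized counts: Pearson r with the
two-sided t-based p on n − 2 degrees of freedom; |r| = 1 maps to p = 0;
pairs with fewer than 3 complete observations or zero variance are kept
in the table with `NA` correlation. A pair touching several features of
one gene gets the highest-ranked class. Summaries report, per class, the
annotation count, hierarchy-assigned DMR count, the number of DMRs with a
significant (p < 0.05) correlation, that percentage to one decimal, and
the number with significant negative correlations.

# The synthetic study

The generator produces paired inputs with planted truth so every stage is
testable without external data. Defaults are the study conditions the
pipeline targets, with the remaining free choices made once on
field-realism grounds:

* genome: 2 contigs x 500 kb; 40 non-overlapping genes, lengths
  U(800, 8000) bp so some genes are shorter than the 1.5 kb gene-start
  span; random strands; CpGs as a thinned point process at 0.02/bp,
  tripled within ±500 bp of each TSS (CpG-island-like enrichment);
* methylation: background level 0.78 with a dip to 0.2 within ±500 bp of
  each TSS; coverage Poisson with mean 5X; methylated counts
  beta-binomial with concentration 30 (visible overdispersion beyond
  binomial, as bisulfite data show);
* planted DMRs: 20 regions of exactly 22 consecutive CpGs — the scale of
  the candidate DMRs the motivating study reports (~774 bp, 22 CpGs on
  average) — placed inside gene features chosen by the coupling table's
  weights, shifting the two groups by ±0.15 each (|Δβ| = 0.3 total);
* samples: 5 large + 5 small, split between two feed strata;
* expression: per-gene baseline log-mean U(log 50, log 500),
  negative-binomial dispersion 0.05; genes carrying a planted DMR are
  coupled with log-scale strength 1.2 through the *noise-free*
  methylation of the planted feature, standardized across samples —
  promoter-proximal classes (P1/GS/P6) couple negatively, gene body and
  TTR with a random sign per gene. Acting through true rather than
  observed methylation keeps the attenuation of observed correlations by
  sequencing noise realistic and measurable.

What passing tests on this generator do and do not show: the synthetic
data have independent CpGs given the design (no local co-methylation
beyond the planted structure), deterministic group-level true levels (no
per-individual random methylation effects), no read-level artifacts
(bisulfite conversion failure, M-bias, mapping bias), and clean NB
expression without RNA degradation. Recovery and calibration results
therefore validate the machinery — coordinate handling, statistics,
permutation calibration, bookkeeping — not robustness to those real-data
pathologies.

# Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 in is 1-based
  inclusive, BED out is 0-based half-open; coverage-format text is
  1-based.
* All stochastic stages take explicit seeds; permutation enumeration is
  exhaustive whenever the distinct-relabeling count fits the budget, so
  small-n runs are fully deterministic. Two pipeline runs with one config
  are byte-identical, and a rerun over an unchanged output directory is
  served from the manifest cache.
* Duplicate positions within one sample are summed with a warning; loci
  observed in no sample are never materialized.
* Degenerate inputs have defined behaviour throughout: empty matrices
  pass through filters, constant vectors raise explicit
  undefined-correlation errors, zero delta beta warns, strata missing a
  group are dropped with a warning (an error if none remain).
* Problem sizes in the test-suite and acceptance runs (1 Mb genome,
  ~21,000 CpGs, 10 samples, 1000-permutation budgets) were chosen so the
  full suite completes in about a minute while every statistical check
  retains enough resolution to be meaningful; they are stated here as the
  package's reference desk-scale conditions.

# Known limitations

Single-factor two-group designs only (one stratifying covariate); no
per-transcript TSS handling; no non-CpG contexts beyond pass-through; the
pooled permutation null is conservative under dense signal (see above);
and the DE module's t-test on log-transformed normalized counts is a
deliberate simplification that should not be used as a stand-alone DE
tool at very small counts.
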