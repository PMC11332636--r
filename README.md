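# methylink

Genome-wide integration of DNA methylation (whole-genome bisulfite
sequencing) with gene expression (RNA-seq) for two-group designs — e.g.
divergent growth phenotypes in Atlantic salmon gut epithelium — at
realistic sequencing depth (~5X) and small sample size, where region-level
statistics with permutation calibration are the appropriate tool.

The package covers the full analysis path:

* **Methylation IO** — Bismark coverage / cytosine-report parsing, CpG
  destranding, cross-sample matrix assembly, complete-coverage filtering.
* **Global patterns** — 10 kb genome tiling with CpG-count and coverage
  filters, PCA of tile methylation, PERMANOVA between groups, and a
  50 bp-binned TSS metaprofile (−6 kb … +5 kb).
* **DMR detection** — candidate differentially methylated regions from
  smoothed per-CpG group differences (stratified by a nuisance covariate
  such as feed type), region construction over consecutive CpGs
  (|Δ| ≥ 0.05, ≥ 5 CpGs, gaps ≤ 1 kb), a variance-standardized region
  statistic, and a pooled within-stratum label-permutation null:
  `p = (1 + #{|stat_null| ≥ |stat_obs|}) / (1 + N_null)`, exhaustive
  enumeration whenever feasible, raw p < 0.01 defining candidates
  (deliberately unadjusted).
* **Genomic features** — strand-aware intervals per gene: proximal
  promoter `P1` (−1 kb…TSS), distal promoter `P6` (−6 kb…−1 kb), gene
  start `GS` (first 1.5 kb), gene body `GB` (remainder), terminal region
  `TTR` (1 kb past the TTS); annotation of DMRs with double bookkeeping
  (`N_A` interactions vs hierarchy-assigned `N_DMRs`,
  P1 > GS > P6 > GB > TTR > Intergenic) and per-feature DMR density.
* **Expression** — count filtering, median-of-ratios size factors,
  normalized counts, covariate-adjusted differential test with BH
  correction, MA/volcano tables.
* **Integration** — per (DMR, gene) Pearson correlation of mean DMR
  methylation against normalized counts (significance at p < 0.05),
  summarized per feature class.
* **Synthetic data** — a generator with planted truth (TSS methylation
  dips over a 78% background, beta-binomial 5X coverage, planted DMRs
  with |Δβ| = 0.3, feature-dependent methylation–expression coupling)
  so every stage is testable end to end without any downloads.

## Worked example

Simulate a paired study (2 × 500 kb genome, 40 genes, 5 large vs 5 small
samples in two feed strata, 20 planted DMRs) and run the whole pipeline:

```r
library(methylink)

ds <- simulate_dataset(sim_config(seed = 42), dir = "demo/data")
cfg <- pipeline_config(
  gff = ds$paths$gff, coverage = ds$paths$coverage,
  counts = ds$paths$counts, metadata = ds$paths$metadata,
  outdir = "demo/out", min_count = NULL, seed = 42)
rep <- run_pipeline(cfg)

round(global_methylation_summary(rep$matrix), 3)
#>   s01   s02   s03   s04   s05   s06   s07   s08   s09   s10
#> 0.717 0.717 0.718 0.719 0.715 0.715 0.717 0.714 0.715 0.715

with(rep$permanova,
     cat(sprintf("PERMANOVA: R2 = %.3f, p = %.3f (%d permutations)\n",
                 r_squared, p, n_perm)))
#> PERMANOVA: R2 = 0.251, p = 0.008 (251 permutations)

cat(sprintf("candidate DMRs: %d of %d tested regions\n",
            sum(rep$dmrs$candidate), nrow(rep$dmrs)))
#> candidate DMRs: 20 of 173 tested regions

summarize_tables("demo/out")
#> DMR annotation per genomic feature
#>     Feature     N_A N_DMRs Density
#>          P6       3      2   0.000
#>          P1       7      7   0.007
#>          GS 10 (+1)      4   0.003
#>          GB      10      7   0.002
#>         TTR       3      0   0.000
#>  Intergenic       -      0       -
#>       Total      34     20       -
#>
#> Methylation-expression correlation per genomic feature
#>  Feature N_A N_DMRs Significant Proportion Negative
#>       P1   7      7           7      100.0        7
#>       GS  11      4           4      100.0        2
#>       P6   3      2           2      100.0        2
#>       GB  10      7           7      100.0        4
#>      TTR   3      0           0          -        0
#>    Total  34     20          20          -       15
```

Reading the output: per-sample global methylation sits near the simulated
background (the TSS dips pull it below 0.78); the PERMANOVA detects the
planted group structure; all 20 candidate DMRs are the planted regions
(`N_DMRs` column, assigned by the hierarchy, with `N_A` counting every
DMR–gene–feature interaction and the `(+1)` marking a gene shorter than
1.5 kb whose whole length is gene start); and every candidate's mean
methylation correlates significantly with its gene's normalized
expression — negatively for all promoter-proximal links, as planted.
`demo/out/` additionally holds per-stage tables (tiles, PCA scores, TSS
metaprofile, DMR list, DE results, links) and a `manifest.json` with
input checksums, parameters and stage timings; rerunning with unchanged
inputs is served from this cache.

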