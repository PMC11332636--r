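Package: methylink
Title: Integration of Whole-Genome Bisulfite Methylation with Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide integration of CpG methylation
    (whole-genome bisulfite sequencing) with gene expression (RNA-seq).
    Reads Bismark-style cytosine reports, destrands CpG calls and assembles
    cross-sample methylation matrices; tiles the genome, runs PCA and
    PERMANOVA on tile methylation, and computes TSS-centred methylation
    metaprofiles; detects candidate differentially methylated regions
    (DMRs) between groups with a smoothed-difference, stratified
    label-permutation caller; builds strand-aware promoter, gene-start,
    gene-body and terminal-region intervals from GFF3 gene models;
    normalizes RNA-seq counts by median-of-ratios and runs a simple
    covariate-adjusted differential-expression test; and correlates
    per-DMR mean methylation with normalized expression, summarized by
    genomic feature. A synthetic-data generator with planted truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    withr,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
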