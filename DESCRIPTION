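Package: retroDE
Title: Locus-Level LINE-1 Expression Outlier Analysis Without Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploratory, per-sample analysis of locus-level
    full-length LINE-1 (L1) retrotransposon expression in bulk RNA-seq
    cohorts that lack biological replicates. Implements median-of-ratios
    normalization with expressed-feature filters, per-sample z-score
    differential expression against a control distribution with
    leave-one-out handling for controls, net-upregulation scoring,
    genomic-context classification of L1 loci (exonic, intronic,
    intergenic) with host-gene assignment, host-gene anticorrelation
    summaries, resampling-based gene-set enrichment, a shared read-pair
    fragment statistic for detecting L1 exonization, retained-intron
    filtering, and scale-regions signal profiles over region sets. A
    seeded negative-binomial simulator generates annotation, count
    matrices, paired-fragment tables and signal tracks with injected
    effects so every stage is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
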