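Package: nueseq
Title: Negative-Binomial Differential Expression and Expression-Pattern
    Classification for Contrasting Nitrogen-Use-Efficiency Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained RNA-seq analysis pipeline for a two-genotype by
    two-condition factorial contrasting a high and a low nitrogen-use-efficiency
    (NUE) genotype under nitrogen deficit. Implements median-of-ratios size
    factors, method-of-moments negative-binomial dispersion estimation, a
    conditional exact test for two-group differential expression,
    Benjamini-Hochberg adjustment, signed fold changes and FPKM; set algebra
    over the four canonical contrasts to isolate genotype-unique stress
    responders; and a ratio-plane classification of unique responders into
    frontloaded, stress-tolerance and relatively-upregulated genes, with a
    chi-squared direction-consistency test. Ships a negative-binomial count
    simulator with planted expression archetypes and recovery scoring, plus
    replicate-correlation QC and qPCR 2^-ddCt concordance checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
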