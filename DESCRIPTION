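Package: polysomeTE
Title: Translation Efficiency Analysis from Polysome-Profiling RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying translational control from paired
    total and polysome-fraction RNA-seq count data. Implements
    median-of-ratios normalization, per-gene translation efficiency
    (TE) estimation, moderated Wald tests for TE changes over time and
    for strain-by-time interactions, threshold-based classification of
    translationally regulated gene sets, ATG-dependent upstream open
    reading frame (uORF) scanning of 5' leader sequences with an exact
    binomial proportion test, and hypergeometric term
    over-representation analysis. A negative-binomial simulator with
    planted mRNA and TE effects and controlled uORF placement provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: RNASeq, GeneExpression, Normalization, DifferentialExpression,
    Translation, Sequencing, Software
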