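Package: riboshift
Title: TRAP-Seq Translatome Analysis of Atherogenic Endothelium
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for translating ribosome
    affinity purification (TRAP) sequencing studies of endothelium under
    low and disturbed flow. Provides fraction-purity quality control by
    marker transcript depletion, a negative-binomial Wald test for
    differential expression with median-of-ratios normalization, a
    ribosome-versus-total delta statistic that ranks translational
    shifts, percent-spliced-in (PSI) estimation from junction counts
    with a beta-binomial delta-PSI test, expression-matched 6-mer RNA
    binding protein motif enrichment in exon flanks, an LFC-thresholded
    concordance analysis for genotype-dependent translational programs,
    and hypergeometric over-representation analysis. A seeded synthetic
    data generator with machine-readable ground truth emulates the
    paired two-fraction, two-condition, two-genotype design so every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: RNASeq, DifferentialExpression, AlternativeSplicing,
    SequenceMatching, QualityControl, Software
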