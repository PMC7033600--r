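Package: polycalib
Title: Spike-In Calibrated Analysis of Polycomb Chromatin Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spike-in (exogenous genome) calibrated analysis of
    Polycomb chromatin data: dual-genome calibration factors with input/gDNA
    mixing-ratio correction, spike-anchored size factors for negative-binomial
    Wald differential testing (including two-factor interaction designs),
    Polycomb peak filtering and target-gene classification, promoter Capture-C
    fragment digestion, normalization and interaction-peak merging, and 3D
    segmentation and quantification of nuclear Polycomb bodies. Includes a
    synthetic-data module that generates every input the pipeline consumes
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    tiff,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2,
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
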