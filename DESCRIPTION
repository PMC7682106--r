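Package: phaseomics
Title: Growth-Phase Expression Dynamics for Bacterial Multi-Omics Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for growth-phase resolved transcriptome and
    proteome time courses of filamentous bacteria such as Actinoplanes sp.
    SE50/110. Provides pooled-reference relative abundance (M-value) tables
    with per-time-point significance calls, operon and transcription start
    site (TSS) inference from strand-specific coverage tracks, promoter -10/-35
    motif discovery by expectation maximization, Ward hierarchical clustering
    of time-course profiles with Krzanowski-Lai model selection, cross-omics
    cluster co-occurrence and lagged transcript-protein correlation, and
    specific product formation rates from growth data. A synthetic data
    generator with planted ground truth (operons, TSS, promoters, expression
    archetypes, transcript-protein lags) drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
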