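Package: devexpr
Title: Replicate-Calibrated Developmental Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq profiles of a four-stage
    life cycle sequenced without biological replicates. Implements depth
    normalization to a reference library, a k*sqrt(N) sampling-error
    envelope with replicate-concordance calibration of the detection
    threshold, Monte-Carlo fold-change cutoffs at stated false-calling
    rates, stage-specific and settlement-specific t-tests on log counts,
    noise-gated pairwise transition classification, resampling-based term
    enrichment with Benjamini-Hochberg correction, the top-25-percent-of-
    range stage-enrichment statistic with Fisher's exact test, exon,
    intron and intergenic read attribution against gene models, normalized
    coverage track export, delta-delta-Ct qPCR concordance checks, and a
    synthetic data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
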