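Package: baserecal
Title: Base Quality Score Recalibration for Aligned Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recalibrates per-base quality scores in BAM files of aligned
    short-read sequencing data so that they reflect empirical sequencing-error
    probabilities. A logistic regression error model is trained on a
    user-chosen genomic region: bases are labeled as errors by comparison to
    the reference, known-variant positions are excluded, and positions whose
    non-reference allele count exceeds a coverage-dependent threshold are
    removed as likely novel variants or systematic alignment artifacts. The
    fitted model (covariates: reported quality, a zero-quality indicator,
    read mean quality, read position, base identity, and indicators for
    high-error read positions) rewrites every base quality on the Phred
    scale. Calibration diagnostics include per-quality empirical error
    rates, the frequency-weighted squared error (FWSE), error/variant
    discrimination AUC, and a four-panel diagnostic figure. A read simulator
    with truth labels supports validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    data.table,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
SystemRequirements: samtools (for BAM output conversion and indexing)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
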