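Package: plastidCES
Title: Chloroplast Translatome Analysis of Assembly-Dependent Translational Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chloroplast translation output and transcript
    accumulation from tiling-microarray probe intensities and tier-assigned
    sequencing alignments, computes translation-efficiency fold changes with
    empirical-Bayes moderated t-statistics and Benjamini-Hochberg FDR control,
    derives percentile-based fold-change cut-offs, and classifies genes as
    primary lesions, operon-coupled effects, or feedback-regulation candidates
    (control by epistasy of synthesis, CES). Includes a ground-truth-known
    synthetic data generator (miniature circular plastome, two-channel probe
    tables, per-tier SAM alignments) so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    data.table,
    withr,
    yaml,
    jsonlite,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
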