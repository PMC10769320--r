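Package: fiberhmm
Title: Single-Molecule Chromatin Footprint Calling from m6A-Marked Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls protein footprints on individual chromatin fibers from
    single-molecule adenine-methylation (m6A) data using a two-state hidden
    Markov model with sequence-context-specific emission probabilities
    calibrated from methylated naked-DNA and untreated controls. Classifies
    decoded footprints into nucleosome, preinitiation-complex (PIC),
    promoter-proximal paused polymerase (PPP), elongating Pol II and
    Pol III transcription-associated footprints using nascent-RNA peak
    annotations; quantifies pause-associated nucleosome architecture with
    Gaussian-mixture positioning and matched subsampling; and measures
    single-fiber co-occupancy coordination between regulatory elements with
    Fisher exact contingency statistics. Includes a synthetic fiber
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
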