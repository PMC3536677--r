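Package: notchpulse
Title: Integrative Analysis of Transcriptional Responses to a Short Notch Pulse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide responses to a brief pulse of
    Notch pathway activation: normalization and spline F-test differential
    expression for replicated two-colour timecourse microarrays,
    Dirichlet-process Gaussian mixture clustering of temporal expression
    profiles with the number of clusters estimated from the data, run-length
    peak calling on tiling-array ChIP enrichment tracks, RNA polymerase II
    pausing-state classification (unbound / poised / active poised / active
    uniform), association of CSL/Su(H) binding peaks with genes, logistic
    modelling of differential-expression odds, and Su(H)/Hairy motif and
    paired-site (SPS) scanning. Includes a synthetic-data generator with
    planted ground truth so every stage can be exercised end-to-end, and a
    pipeline that assembles the master per-gene summary table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    yaml,
    stats,
    splines,
    tools,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
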