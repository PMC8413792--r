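Package: nirsconn
Title: Functional Connectivity Analysis of fNIRS Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Graph-theoretical functional-connectivity analysis of
    multichannel continuous-wave functional near-infrared spectroscopy
    (fNIRS) recordings from a block-design finger-tapping protocol measured
    before and after sleep deprivation. Provides SNIRF input/output,
    hemodynamic preprocessing (wavelet-based motion-artifact suppression,
    zero-phase Butterworth low-pass filtering, the modified Beer-Lambert
    law, correlation-based signal improvement), Pearson connection matrices
    under absolute, cost and surrogate thresholding, binary and weighted
    network metrics (density, clustering coefficient, global efficiency),
    fully-within repeated-measures ANOVA with sphericity diagnostics,
    Dunnett-style comparisons against rest, brain-behavior correlation of
    task-related connectivity changes with cognitive scores, and a
    synthetic-cohort generator that emulates the recording protocol for
    testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
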