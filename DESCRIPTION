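Package: germcycle
Title: Cell Cycle Phase Durations for Germarium Stem Cells from FUCCI Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute cell-cycle phase durations (G1, S, G2, M) for
    Drosophila ovarian follicle stem cells from short live-imaging windows of
    FUCCI reporter tracks, using a renewal-style dwell-time/exit estimator that
    is unbiased under length-biased sampling of an asynchronous population.
    Also scores fixed-snapshot FUCCI/EdU/DAPI tables into phase-fraction tables
    with N-1 chi-squared comparisons and EdU-index normalization, converts
    cycle times into follicle-cell and escort-cell production rates and
    division/differentiation flux balances, quantifies H2B-RFP label dilution
    to count divisions, and ships a seeded synthetic cell-population simulator
    (steady-state phase occupancy, finite imaging windows, reporter onset lags,
    EdU pulses, two-fold-per-division label dilution) so every stage of the
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
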