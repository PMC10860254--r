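Package: cephmetrics
Title: Cephalometric Landmark Accuracy, Reliability and Device-Comparison Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing manually traced lateral cephalograms: the
    Muenster 22-item cephalometric measurement engine (angles, calibrated
    millimetre distances and ratios computed from 33 named landmarks,
    including the constructed points Gnk and Xi), landmark localisation
    accuracy as mean radial error (MRE) and successful detection rate (SDR),
    interrater reliability via the two-way absolute-agreement intraclass
    correlation ICC(A,k), linear mixed-effects device-comparison models with
    likelihood-ratio model selection, and a synthetic-study generator that
    emulates student landmark submissions with landmark-specific placement
    error so the whole pipeline can be exercised end to end. Submissions are
    read from a documented JSON export format; all user-facing functions
    take and return tidy data frames.
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
    lme4,
    openssl,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
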