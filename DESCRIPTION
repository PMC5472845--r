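Package: gustadapt
Title: Adaptive Yes-No Estimation of Gustatory Detection Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two adaptive yes-no procedures for rapid estimation of
    taste detection thresholds on prepared dilution series: a modified
    single-interval adjustment-matrix (SIAM) staircase with an initial boost
    phase, blank scheduling and reversal-mean threshold extraction, and a
    grid-based Bayesian QUEST variant (Weibull psychometric function,
    posterior-mean threshold, confidence-interval stopping rule) constrained
    to the prepared concentrations. Includes log-equidistant dilution-series
    construction, simulated Weibull observers, full-session drivers with
    study-design bookkeeping and exclusion rules, test-retest reliability
    analysis, and a Monte-Carlo validation harness for the operating points
    of both procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
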