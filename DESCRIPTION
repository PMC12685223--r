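Package: wsindypop
Title: Weak-Form Equation Learning for Structured Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns age- and size-structured population models from noisy
    time-series histogram data using weak-form sparse identification of
    nonlinear dynamics (WSINDy). Provides a flux-limited finite-volume
    simulator for transport-source models with renewal (birth) boundary
    conditions, multiplicative log-normal noise generation with closed-form
    noise-to-signal calibration and total-population debiasing, weak-form
    assembly of stacked PDE/ODE linear systems over candidate vital-rate
    libraries, modified sequential-thresholding least squares (MSTLS) with
    boundary-bagging cross-validation, recovery metrics, and scripted
    reproduction of the reference computational studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
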