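Package: normadapt
Title: Multi-Timescale Divisive Normalization Models of Adaptive Value
    Coding and Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates cascaded fast/slow divisive-normalization circuits
    of value coding and analyses the choice behavior they predict.
    Provides a Runge-Kutta integrator for the coupled
    excitatory/inhibitory rate equations, a generator of synthetic
    two-alternative choice sessions with narrow- and wide-variance
    reward blocks, sigmoid choice-curve fitting, and session-level
    adaptation statistics including timescale-ratio sweeps and
    magnitude/ITI permutation nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
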