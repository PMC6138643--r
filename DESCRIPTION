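Package: protodyn
Title: Predicting Proteome Dynamics from Gene Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts dynamic protein abundance time-courses from gene-expression
    time-courses and protein half-lives under a periodic (return-to-baseline)
    boundary condition instead of the steady-state assumption. Implements the
    trapezoidal recurrence for the linear synthesis-degradation kinetic model
    solved by fixed-point iteration over one period, consensus-period estimation
    via a floating-mean periodogram for unevenly sampled series, correction of
    noisy (possibly negative) measured protein half-lives via a truncated-normal
    error model, steady-state versus time-course translation-rate comparison, and
    detection of post-translational regulation by fitting a periodic step-function
    half-life to measured protein profiles. Includes a seeded synthetic-data
    generator with closed-form oracles so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
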