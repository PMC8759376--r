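Package: acuitykit
Title: Clinimetric Evaluation of Tactile-Acuity Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates psychophysical observers and tactile-acuity testing
    sessions (an adaptive two-point discrimination staircase and vibrotactile
    localisation/orientation tests on a twelve-node neck array) and evaluates
    the resulting scores clinimetrically: two-way random-effects ANOVA variance
    components, intraclass correlations ICC(2,1) and ICC(2,k) with
    F-distribution confidence intervals, standard error of measurement,
    coefficient of variation, the smallest-detectable-change family,
    floor/ceiling diagnostics via tail percentages and skewness z-scores,
    enter-model multiple regression with semi-partial correlations, and
    sequential two-mediator mediation with percentile bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
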