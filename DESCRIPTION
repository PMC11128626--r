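Package: mrmediate
Title: Two-Step Mediation Mendelian Randomization with Drug-Target Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample, two-step (mediation)
    Mendelian randomization from GWAS summary statistics. Covers reading and
    harmonizing summary-statistic tables, instrument selection (significance
    filtering, greedy LD clumping, F-statistic screening, confounder removal),
    Bayesian colocalization via approximate Bayes factors, a five-estimator
    causal panel (inverse-variance weighted, MR-Egger, weighted median, simple
    and weighted mode) with a sensitivity suite (Cochran's Q, Egger intercept,
    leave-one-out, MR-PRESSO), product-of-coefficients mediation with delta and
    Monte-Carlo intervals, and a seeded summary-level simulator with known
    ground truth for validating every stage.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
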