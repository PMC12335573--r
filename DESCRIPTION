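Package: humalign
Title: Human-AI Confidence Alignment in Assisted Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for AI-assisted binary
    decision-making experiments in which the degree of alignment between AI
    confidence and human confidence is steered experimentally. Provides an
    exact Wallenius noncentral hypergeometric engine for biased
    card-sampling, a calibrated-by-design game generator, a synthetic
    participant simulator, alignment-error metrics (maximum and expected
    alignment error over the joint confidence lattice), multicalibration of
    AI confidence via uniform-mass histogram binning within human-confidence
    subgroups, and utility analysis through conditional matching rates,
    Bayesian binomial mixed-effects A/B tests, and Boschloo's exact test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    rjags,
    coda,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
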