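Package: spheroidstruct
Title: Structure and Growth Inference for Avascular Tumour Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of tumour-spheroid structure built around
    Greenspan's classical model of avascular growth. Provides the structural
    model linking outer radius to the relative sizes of the inhibited region
    and necrotic core, the growth ODE and its semi-analytic steady state with
    closed-form inversion and analytic sensitivities; a multivariate-normal
    observation model with plug-in covariances; likelihood-based inference
    (maximum likelihood, profile-likelihood confidence intervals,
    likelihood-ratio equivalence tests, and confidence-region boundary
    tracing); a total-least-squares linear model for phase-3 trajectories
    with a latent progression variable; and a synthetic cohort generator
    emulating multi-density spheroid seeding experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
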