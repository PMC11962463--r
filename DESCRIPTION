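Package: emamot
Title: Day-to-Day Motivation and Effort-Based Decision-Making from
    Ecological Momentary Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intensive-longitudinal (ecological momentary
    assessment) studies of motivational state and effort-based choice.
    Provides a synthetic cohort generator emulating a two-week smartphone
    protocol (twice-daily Likert state reports, alternate-day effort-reward
    discounting games), descriptive analytics for state dynamics
    (repeated-measures correlation, between-person associations, weekday
    structure, autocorrelation and inertia), task validity and reliability
    checks (rank ANOVA of discounting, success stability, effort
    calibration, pairwise-game ICC, practice-effect comparison), mixed-model
    analyses of choices and vigor, and a joint hierarchical Bayesian model
    coupling a one-parameter item-response-theory latent motivational state
    to a state-modulated linear effort-discounting choice model, fitted by
    Hamiltonian Monte Carlo with highest-density-interval and
    probability-of-direction posterior summaries, posterior-predictive
    checks, lagged-state comparisons, and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
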