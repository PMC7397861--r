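Package: actionprior
Title: Precision-Weighted Observer Models of Action-Outcome Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for visuomotor tasks in which
    participants aim a force-controlled cursor at a target and intermittently
    estimate their own action outcomes. Implements the task geometry and trial
    scheduling, a synthetic-cohort generator with known ground truth,
    median-absolute-deviation preprocessing, repeated-measures ANOVA with
    generalized eta-squared, linear mixed models of the estimation-error /
    performance-error weighting slope selected by conditional AIC,
    hierarchical Bayesian observer models (precision-weighted combination of
    a target-centered prior with shifted sensory evidence) estimated by MCMC
    with split R-hat diagnostics and WAIC comparison, posterior predictive
    checks, parameter-recovery scoring, and trait-association statistics
    (partial correlations, Holm correction, Jeffreys exact correlation Bayes
    factors, and exact power analysis for correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
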