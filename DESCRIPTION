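Package: baclopk
Title: Population and Noncompartmental Pharmacokinetics of Baclofen Under
    Herbal Pretreatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a rat drug-herb interaction
    study of oral baclofen. Implements the two-compartment first-order
    absorption model with urinary excretion (closed-form and ODE solvers),
    a synthetic-study generator with log-normal between-subject variability
    and combined additive/proportional residual error, noncompartmental
    analysis (Cmax, Tmax, lambda-z, AUC, clearance, urinary recovery,
    absolute bioavailability), population estimation by an
    importance-sampling Monte Carlo parametric EM algorithm with
    group-specific absorption rate and bioavailability, and model
    diagnostics (visual predictive checks, normalized prediction
    distribution errors, group comparisons by t-tests and ANOVA with
    Scheffe post hoc contrasts).
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
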