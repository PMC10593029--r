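Package: vesimlab
Title: Simulation Laboratory for Vaccine-Effectiveness Estimands and
    Study-Design Biases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how epidemiologic study designs (challenge
    trials, randomized trials, cohorts, contact tracing, post-exposure
    progression studies, severity pyramids) recover the causal parameters
    needed to parameterize an individual-based infectious-disease
    transmission model. Provides exact algebra linking marginal, composite
    and conditional vaccine-effectiveness measures (including the
    conversion VE_H|S = 1 - (1 - VE_SH)/(1 - VE_S)), enumeration of
    feasible post-exposure outcome vectors under precedence constraints,
    conversion between joint and conditional outcome-probability tables,
    a structural-causal-model simulator with per-individual potential
    outcomes under both vaccination arms, design emulators with
    observational masking, stratified risk-ratio estimators, and packaged
    experiments demonstrating collider/selection bias from conditioning
    on post-exposure events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
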