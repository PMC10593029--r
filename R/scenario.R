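#' Scenario configurations for the structural causal model
#'
#' A scenario configuration fully specifies the data-generating process the
#' simulator draws from: covariate laws, the vaccination assignment
#' mechanism, the exposure mechanism (including the variant mixture per
#' calendar period and an optional behavioural effect of vaccination on
#' exposure), a multiplicative per-event risk model, an individual-level
#' frailty, and misclassification of measured covariates. Because the model
#' is structural, every simulated individual carries potential outcomes
#' under both vaccination arms, so all causal estimands have computable
#' ground truth.
#'
#' The default chain used by scenarios extends the shipped [event_chain()]
#' with the pair `(S, H)`: hospitalization for the disease implies
#' symptomatic disease. This is what makes the conversion
#' `VE_H|S = 1 - (1 - VE_SH)/(1 - VE_S)` an identity between marginal and
#' conditional risk ratios (the conversion presumes every hospitalized case
#' is symptomatic).
#'
#' The risk model is multiplicative: the conditional probability of each
#' event, given that its prerequisite events occurred, is a baseline times
#' multipliers for covariates, variant, vaccination and frailty, clipped to
#' `[0, 1]` with a clip counter reported on the simulated population.
#'
#' @param chain [event_chain()] used by the scenario.
#' @param covariates Named list of covariate laws. Each law is one of
#'   `list(type = "categorical", levels =, probs =)`,
#'   `list(type = "bernoulli", p =)`, `list(type = "poisson", lambda =)`.
#'   `calendar_time` must be categorical with integer-like levels.
#' @param vaccination `list(mechanism = "randomized", p =)` or
#'   `list(mechanism = "confounded", intercept =, coef = list(...))`, where
#'   `coef` holds logistic coefficients: a named vector over levels for
#'   categorical covariates, a scalar for binary/count covariates.
#' @param exposure `list(p =, rr_vaccinated =, variants =, mixture =)`;
#'   `mixture` is a named list, one entry per calendar period, each a named
#'   probability vector over `variants` summing to 1. `rr_vaccinated`
#'   multiplies the exposure probability of the vaccinated (a behavioural
#'   pathway; 1 = blinded/no effect).
#' @param risk `list(baseline =, rr_vaccination =, modifiers =,
#'   vacc_interaction =)`. `baseline` and `rr_vaccination` are named
#'   vectors over events. Each modifier is `list(field =, rr =)` with `rr`
#'   a named vector over events (binary/count fields; applied as
#'   `rr^value`) or a named list `level -> named vector` (categorical
#'   fields). `vacc_interaction`, if given, is `list(field =, rr =)` with a
#'   named vector over events: an extra multiplier on the *vaccinated* risk
#'   when the (binary) field is 1, encoding heterogeneous vaccine effects
#'   (e.g. attenuated protection in high-risk hosts).
#' @param frailty_sd Standard deviation of log frailty (one log-normal
#'   multiplicative susceptibility factor per individual, shared across all
#'   events, mean 1). 0 disables frailty.
#' @param misclassification Named list with entries `variant` and
#'   `immunocompromised`, each `c(sensitivity =, specificity =)`. For
#'   variants the last level of `exposure$variants` is the "positive" call
#'   (an S-gene-target-failure-style binary proxy).
#' @param observation `list(risk_factor_measured =)`: whether the binary
#'   `risk_factor` covariate appears in study-design outputs (FALSE =
#'   unmeasured common cause).
#' @param seed Integer root seed; all stochastic operations derive child
#'   streams from it by fixed labels.
#' @return A list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config()
#' pop <- sample_population(cfg, n = 500)
#' @export
scenario_config <- function(chain = default_scenario_chain(),
                            covariates = default_covariate_laws(),
                            vaccination = list(mechanism = "randomized",
                                               p = 0.5),
                            exposure = default_exposure(),
                            risk = default_risk_model(),
                            frailty_sd = 0,
                            misclassification = list(
                              variant = c(sensitivity = 1, specificity = 1),
                              immunocompromised = c(sensitivity = 1,
                                                    specificity = 1)
                            ),
                            observation = list(risk_factor_measured = TRUE),
                            seed = 1L) {
  cfg <- structure(
    list(chain = chain, covariates = covariates, vaccination = vaccination,
         exposure = exposure, risk = risk, frailty_sd = frailty_sd,
         misclassification = misclassification, observation = observation,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
  validate_scenario(cfg)
  cfg
}

#' @rdname scenario_config
#' @export
default_scenario_chain <- function() {
  event_chain(requires = list(
    c("I", "S"), c("I", "D"), c("S", "H"), c("D", "H"),
    c("H", "C"), c("H", "M")
  ))
}

#' @rdname scenario_config
#' @export
default_covariate_laws <- function() {
  list(
    age_group = list(type = "categorical",
                     levels = c("18-49", "50-64", "65+"),
                     probs = c(0.55, 0.25, 0.20)),
    sex = list(type = "categorical", levels = c("F", "M"),
               probs = c(0.5, 0.5)),
    comorbidity_count = list(type = "poisson", lambda = 0.8),
    prior_infection = list(type = "bernoulli", p = 0.30),
    immunocompromised = list(type = "bernoulli", p = 0.04),
    risk_factor = list(type = "bernoulli", p = 0),
    calendar_time = list(type = "categorical", levels = c("1", "2"),
                         probs = c(0.5, 0.5))
  )
}

#' @rdname scenario_config
#' @export
default_exposure <- function() {
  list(
    p = 0.25,
    rr_vaccinated = 1,
    variants = c("delta", "omicron"),
    mixture = list(`1` = c(delta = 0.9, omicron = 0.1),
                   `2` = c(delta = 0.2, omicron = 0.8))
  )
}

#' @rdname scenario_config
#' @export
default_risk_model <- function() {
  ev_named <- function(...) {
    x <- c(I = 1, S = 1, D = 1, H = 1, C = 1, M = 1)
    dots <- c(...)
    x[names(dots)] <- dots
    x
  }
  list(
    baseline = c(I = 0.5, S = 0.6, D = 0.7, H = 0.08, C = 0.25, M = 0.12),
    rr_vaccination = ev_named(I = 0.7, S = 0.6, H = 0.5, M = 0.8),
    modifiers = list(
      age = list(field = "age_group", rr = list(
        `18-49` = ev_named(),
        `50-64` = ev_named(H = 1.5, C = 1.2, M = 1.4),
        `65+`   = ev_named(H = 2.2, C = 1.4, M = 2.0)
      )),
      immunocompromised = list(field = "immunocompromised",
                               rr = ev_named(H = 1.8, M = 1.8)),
      prior_infection = list(field = "prior_infection",
                             rr = ev_named(I = 0.6, S = 0.8)),
      comorbidity = list(field = "comorbidity_count",
                         rr = ev_named(H = 1.1, M = 1.1)),
      variant = list(field = "variant", rr = list(
        delta = ev_named(),
        omicron = ev_named(S = 0.9, H = 0.5, M = 0.6)
      ))
    ),
    vacc_interaction = NULL
  )
}

#' Validate a scenario configuration
#'
#' Checks all probabilities, mixtures and rates, collecting every offending
#' field into a single actionable error message.
#'
#' @param cfg A [scenario_config()].
#' @return `cfg`, invisibly, or an error of class
#'   `vesimlab_validation_error` listing offending fields.
#' @export
validate_scenario <- function(cfg) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  is_prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

  validate_event_chain(cfg$chain)
  ev <- cfg$chain$events

  for (nm in names(cfg$covariates)) {
    law <- cfg$covariates[[nm]]
    switch(law$type,
      categorical = {
        if (abs(sum(law$probs) - 1) > 1e-8 || !is_prob(law$probs))
          note(sprintf("covariates$%s: probs must be a probability vector summing to 1", nm))
        if (length(law$levels) != length(law$probs))
          note(sprintf("covariates$%s: levels and probs lengths differ", nm))
      },
      bernoulli = if (!is_prob(law$p))
        note(sprintf("covariates$%s: p not in [0,1]", nm)),
      poisson = if (law$lambda < 0)
        note(sprintf("covariates$%s: lambda negative", nm)),
      note(sprintf("covariates$%s: unknown law type '%s'", nm, law$type))
    )
  }

  if (!cfg$vaccination$mechanism %in% c("randomized", "confounded")) {
    note("vaccination$mechanism must be 'randomized' or 'confounded'")
  }
  if (cfg$vaccination$mechanism == "randomized" &&
      !is_prob(cfg$vaccination$p %||% NA)) {
    note("vaccination$p not in [0,1]")
  }

  if (!is_prob(cfg$exposure$p)) note("exposure$p not in [0,1]")
  if (cfg$exposure$rr_vaccinated < 0) note("exposure$rr_vaccinated negative")
  periods <- cfg$covariates$calendar_time$levels
  for (pd in periods) {
    mix <- cfg$exposure$mixture[[pd]]
    if (is.null(mix)) {
      note(sprintf("exposure$mixture missing period '%s'", pd))
    } else if (abs(sum(mix) - 1) > 1e-8 || !is_prob(unname(mix))) {
      note(sprintf("exposure$mixture[['%s']] must sum to 1", pd))
    } else if (!setequal(names(mix), cfg$exposure$variants)) {
      note(sprintf("exposure$mixture[['%s']] must name every variant", pd))
    }
  }

  if (!is_prob(cfg$risk$baseline) ||
      !setequal(names(cfg$risk$baseline), ev)) {
    note("risk$baseline must be probabilities named after every chain event")
  }
  if (any(cfg$risk$rr_vaccination < 0)) note("risk$rr_vaccination negative")
  for (nm in names(cfg$risk$modifiers)) {
    mod <- cfg$risk$modifiers[[nm]]
    rrs <- if (is.list(mod$rr)) mod$rr else list(mod$rr)
    if (any(unlist(rrs) < 0)) note(sprintf("risk$modifiers$%s: negative rr", nm))
  }
  if (cfg$frailty_sd < 0) note("frailty_sd negative")
  for (nm in names(cfg$misclassification)) {
    m <- cfg$misclassification[[nm]]
    if (!is_prob(m[["sensitivity"]]) || !is_prob(m[["specificity"]]))
      note(sprintf("misclassification$%s: sensitivity/specificity not in [0,1]", nm))
  }

  if (length(problems)) {
    abort(paste0("invalid scenario configuration:\n",
                 paste0("- ", problems, collapse = "\n")),
          class = "vesimlab_validation_error")
  }
  invisible(cfg)
}

#' Read or write a scenario configuration as YAML or JSON
#'
#' @param cfg A [scenario_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scenario()` returns a validated [scenario_config()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(cfg, path) {
  # named atomic vectors must become maps, not sequences, on disk
  namify <- function(x) {
    if (is.list(x)) {
      lapply(x, namify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  x <- unclass(cfg)
  x$chain <- list(
    events = cfg$chain$events,
    requires = lapply(seq_len(nrow(cfg$chain$requires)),
                      function(i) unname(cfg$chain$requires[i, ]))
  )
  x[-1] <- namify(x[-1])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  requires <- x$chain$requires
  if (is.data.frame(requires) || is.matrix(requires)) {
    requires <- lapply(seq_len(nrow(requires)),
                       function(i) as.character(unlist(requires[i, ])))
  } else {
    requires <- lapply(requires, function(p) as.character(unlist(p)))
  }
  num <- function(v) {
    out <- unlist(v)
    stats::setNames(as.numeric(out), names(out))
  }
  risk <- x$risk
  risk$baseline <- num(risk$baseline)
  risk$rr_vaccination <- num(risk$rr_vaccination)
  risk$modifiers <- lapply(risk$modifiers, function(mod) {
    rr <- if (is.list(mod$rr) && all(vapply(mod$rr, length, 1L) > 1)) {
      lapply(mod$rr, num)
    } else {
      num(mod$rr)
    }
    list(field = mod$field, rr = rr)
  })
  if (length(risk$vacc_interaction$field)) {
    risk$vacc_interaction <- list(field = risk$vacc_interaction$field,
                                  rr = num(risk$vacc_interaction$rr))
  } else {
    risk$vacc_interaction <- NULL
  }
  covs <- lapply(x$covariates, function(law) {
    law$probs <- if (!is.null(law$probs)) as.numeric(unlist(law$probs))
    law$levels <- if (!is.null(law$levels)) as.character(unlist(law$levels))
    law[!vapply(law, is.null, TRUE)]
  })
  vacc <- x$vaccination
  if (!is.null(vacc$coef)) vacc$coef <- lapply(vacc$coef, num)
  scenario_config(
    chain = event_chain(as.character(unlist(x$chain$events)), requires),
    covariates = covs,
    vaccination = vacc,
    exposure = list(p = x$exposure$p,
                    rr_vaccinated = x$exposure$rr_vaccinated,
                    variants = as.character(unlist(x$exposure$variants)),
                    mixture = lapply(x$exposure$mixture, num)),
    risk = risk,
    frailty_sd = x$frailty_sd,
    misclassification = lapply(x$misclassification, num),
    observation = x$observation,
    seed = x$seed
  )
}

#' Derive a reproducible child seed from a root seed and a label
#'
#' All stochastic operations in the package draw from streams keyed by
#' fixed labels, so adding an operation never perturbs the draws of others.
#'
#' @param seed Integer root seed.
#' @param label Character stream label.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  p <- 2147483647
  h <- as.numeric(seed) %% p
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% p
  as.integer(h)
}
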