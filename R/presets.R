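#' Canonical scenario presets
#'
#' Ready-made scenario configurations used throughout the test-bench
#' experiments:
#'
#' * `scenario_null()` — the sharp null: every vaccination multiplier is 1,
#'   vaccination randomized. Every design/estimator pair should return VE 0
#'   up to Monte-Carlo error.
#' * `scenario_no_bias()` — the default effective-vaccine scenario with
#'   randomized vaccination, no behavioural exposure effect, no frailty and
#'   perfect measurement: estimates should recover the configured truth.
#' * `scenario_confounded()` — vaccination uptake increases with age and
#'   immunocompromised status, which also raise severity risks: crude
#'   cohort VE is confounded; age/immunocompromised-stratified VE is not.
#' * `scenario_collider()` — a progression-study stress test. A binary
#'   latent `risk_factor` (prevalence `p_risk_factor`) multiplies the
#'   symptom and hospitalization risks and *attenuates* the vaccine's
#'   symptom protection (`interaction` > 1, as for immunosuppressed hosts).
#'   Conditioning on symptoms then selects vaccinated cases enriched in the
#'   risk factor, distorting the conditional VE against hospitalization —
#'   the vaccine can even appear harmful. Setting `risk_factor_measured =
#'   TRUE` allows stratified adjustment.
#' * `scenario_frailty_misclass()` — log-normal shared frailty across
#'   events plus imperfect variant and immunocompromised measurement.
#'
#' @param seed Root seed stored in the configuration.
#' @param rr_s,rr_h Risk-factor multipliers on the symptom and
#'   hospitalization steps.
#' @param interaction Multiplier applied to the *vaccinated* symptom risk
#'   in risk-factor carriers (1 = homogeneous vaccine effect; > 1 =
#'   attenuated protection).
#' @param frailty_sd Standard deviation of log frailty.
#' @param p_risk_factor Prevalence of the latent risk factor.
#' @param risk_factor_measured Whether study designs may observe the risk
#'   factor (FALSE makes it an unmeasured common cause).
#' @return A [scenario_config()].
#' @name scenario_presets
NULL

#' @rdname scenario_presets
#' @export
scenario_null <- function(seed = 1L) {
  risk <- default_risk_model()
  risk$rr_vaccination[] <- 1
  scenario_config(risk = risk, seed = seed)
}

#' @rdname scenario_presets
#' @export
scenario_no_bias <- function(seed = 1L) {
  scenario_config(seed = seed)
}

#' @rdname scenario_presets
#' @export
scenario_confounded <- function(seed = 1L) {
  scenario_config(
    vaccination = list(
      mechanism = "confounded",
      intercept = -1.2,
      coef = list(age_group = c(`18-49` = 0, `50-64` = 1.5, `65+` = 3.0),
                  immunocompromised = 1.0)
    ),
    seed = seed
  )
}

#' @rdname scenario_presets
#' @export
scenario_collider <- function(rr_s = 2.5, rr_h = 6, interaction = 3.5,
                              frailty_sd = 0, p_risk_factor = 0.3,
                              risk_factor_measured = FALSE, seed = 1L) {
  covs <- default_covariate_laws()
  covs$risk_factor$p <- p_risk_factor
  ev <- c("I", "S", "D", "H", "C", "M")
  one <- stats::setNames(rep(1, 6), ev)
  risk <- list(
    baseline = c(I = 0.6, S = 0.35, D = 0.7, H = 0.12, C = 0.2, M = 0.1),
    rr_vaccination = replace(one, c("S", "H"), c(0.25, 0.8)),
    modifiers = list(
      risk_factor = list(field = "risk_factor",
                         rr = replace(one, c("S", "H"), c(rr_s, rr_h)))
    ),
    vacc_interaction = if (interaction != 1) {
      list(field = "risk_factor", rr = replace(one, "S", interaction))
    }
  )
  scenario_config(
    covariates = covs,
    exposure = list(p = 0.5, rr_vaccinated = 1,
                    variants = c("delta", "omicron"),
                    mixture = list(`1` = c(delta = 1, omicron = 0),
                                   `2` = c(delta = 1, omicron = 0))),
    risk = risk,
    frailty_sd = frailty_sd,
    observation = list(risk_factor_measured = risk_factor_measured),
    seed = seed
  )
}

#' @rdname scenario_presets
#' @export
scenario_frailty_misclass <- function(frailty_sd = 0.25, seed = 1L) {
  ev_named <- function(...) {
    x <- stats::setNames(rep(1, 6), c("I", "S", "D", "H", "C", "M"))
    dots <- c(...)
    x[names(dots)] <- dots
    x
  }
  risk <- default_risk_model()
  risk$baseline <- c(I = 0.45, S = 0.5, D = 0.55, H = 0.06, C = 0.2, M = 0.08)
  risk$modifiers$age$rr <- list(
    `18-49` = ev_named(),
    `50-64` = ev_named(H = 1.4, C = 1.2, M = 1.4),
    `65+` = ev_named(H = 1.8, C = 1.4, M = 1.8)
  )
  risk$modifiers$immunocompromised$rr <- ev_named(H = 1.5, M = 1.5)
  risk$modifiers$comorbidity$rr <- ev_named(H = 1.1, M = 1.1)
  scenario_config(
    risk = risk,
    frailty_sd = frailty_sd,
    misclassification = list(
      variant = c(sensitivity = 0.9, specificity = 0.95),
      immunocompromised = c(sensitivity = 0.9, specificity = 0.95)
    ),
    seed = seed
  )
}

#' @rdname scenario_presets
#' @export
default_collider_grid <- function() {
  tibble::tibble(
    label = c("none", "frailty_only", "moderate", "strong"),
    rr_s = c(1, 1, 2, 2.5),
    rr_h = c(1, 1, 3, 6),
    interaction = c(1, 1, 2, 3.5),
    frailty_sd = c(0, 0.8, 0, 0)
  )
}
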