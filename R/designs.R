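#' Study-design emulators
#'
#' Each design function simulates a population from a scenario and then
#' *observes* it the way the named epidemiologic design would: selecting
#' individuals according to the design's entry criterion, reporting measured
#' (possibly misclassified) covariates, and masking everything a real study
#' cannot see — in particular the counterfactual outcome columns and the
#' latent frailty. Estimators therefore cannot leak ground truth: they only
#' ever see the visible rows.
#'
#' * `design_challenge_trial()` — the ideal design: every participant is
#'   deliberately exposed to a chosen variant and vaccination is randomized,
#'   so both the exposure and the intervention are under experimental
#'   control and all six post-exposure events are observed.
#' * `design_rct()` — a blinded placebo-controlled trial: vaccination is
#'   randomized but exposure happens naturally and is *not recorded* in the
#'   visible rows (trials do not measure exposure). Requires a scenario with
#'   no behavioural effect of vaccination on exposure.
#' * `design_cohort()` — an observational emulation: vaccination follows the
#'   scenario's (possibly confounded) assignment mechanism; measured
#'   covariates are reported for adjustment.
#' * `design_contact_tracing()` — follows exposed contacts of known cases;
#'   selection into the sample may depend on measured covariates via
#'   `selection_rule` (non-exchangeable selection is first-class).
#' * `design_progression_study()` — ascertains individuals at a
#'   post-exposure event (e.g. symptoms) and observes only that event and
#'   those downstream of it.
#'
#' @param cfg A [scenario_config()].
#' @param n Number of simulated individuals before selection.
#' @param p_vacc Randomization probability of vaccination.
#' @param variant Variant every challenge participant is exposed to
#'   (default: the first configured variant).
#' @param seed Root seed; defaults to `cfg$seed`.
#' @param selection_rule `NULL` (uniform inclusion) or a function taking the
#'   visible rows and returning non-negative selection weights; individuals
#'   are included with probability proportional to their weight.
#' @param ascertainment_event Event label at which the progression study
#'   ascertains individuals.
#' @return A tibble of class `study_sample` with attributes `design`,
#'   `ascertainment_event`, and `provenance` (seed and selection rule).
#' @name study_designs
NULL

new_study_sample <- function(rows, design, cfg, seed,
                             ascertainment_event = NA_character_,
                             selection = "all") {
  out <- tibble::as_tibble(rows)
  assert_masked(out)
  attr(out, "design") <- design
  attr(out, "ascertainment_event") <- ascertainment_event
  attr(out, "chain") <- cfg$chain
  attr(out, "provenance") <- list(seed = seed, selection = selection)
  class(out) <- c("study_sample", class(out))
  out
}

#' Assert that a table contains no oracle columns
#'
#' Study samples must never expose potential-outcome columns or the latent
#' frailty; this guard makes accidental oracle leakage into an estimator an
#' error rather than a silent bias.
#'
#' @param rows A data frame of observed records.
#' @return `rows`, invisibly, or an error of class `vesimlab_masking_error`.
#' @export
assert_masked <- function(rows) {
  leaked <- grep("_a[01]$|^frailty$|_latent$", names(rows), value = TRUE)
  if (length(leaked)) {
    abort(paste0("study sample exposes counterfactual/latent columns: ",
                 paste(leaked, collapse = ", ")),
          class = "vesimlab_masking_error")
  }
  invisible(rows)
}

measured_covariates <- function(pop, cfg) {
  keep <- c("id", "age_group", "sex", "comorbidity_count", "prior_infection",
            "calendar_time")
  out <- dplyr::select(pop, dplyr::all_of(keep))
  out$immunocompromised <- pop$immunocompromised_measured
  if (isTRUE(cfg$observation$risk_factor_measured)) {
    out$risk_factor <- pop$risk_factor
  }
  out
}

#' @rdname study_designs
#' @export
design_challenge_trial <- function(cfg, n, p_vacc = 0.5, variant = NULL,
                                   seed = cfg$seed) {
  stopifnot(p_vacc > 0, p_vacc < 1)
  variant <- variant %||% cfg$exposure$variants[1]
  cfg2 <- cfg
  cfg2$exposure$p <- 1
  cfg2$exposure$rr_vaccinated <- 1
  cfg2$exposure$mixture <- lapply(
    cfg$exposure$mixture,
    function(m) stats::setNames(as.numeric(cfg$exposure$variants == variant),
                                cfg$exposure$variants)
  )
  cfg2$vaccination <- list(mechanism = "randomized", p = p_vacc)
  pop <- sample_population(cfg2, n, seed = seed)
  rows <- dplyr::bind_cols(
    measured_covariates(pop, cfg2),
    dplyr::select(pop, "vaccinated", "exposed", "variant_measured",
                  dplyr::all_of(cfg$chain$events))
  )
  new_study_sample(rows, "challenge_trial", cfg2, seed)
}

#' @rdname study_designs
#' @export
design_rct <- function(cfg, n, p_vacc = 0.5, seed = cfg$seed) {
  if (cfg$exposure$rr_vaccinated != 1) {
    abort(paste0(
      "scenario has a nonzero effect of vaccination on exposure ",
      "(exposure$rr_vaccinated != 1), which violates the blinding premise ",
      "of a placebo-controlled trial; use design_cohort() for behavioural ",
      "pathways"), class = "vesimlab_design_error")
  }
  cfg2 <- cfg
  cfg2$vaccination <- list(mechanism = "randomized", p = p_vacc)
  pop <- sample_population(cfg2, n, seed = seed)
  # exposure and true variant are not observed in a trial
  rows <- dplyr::bind_cols(
    measured_covariates(pop, cfg2),
    dplyr::select(pop, "vaccinated", dplyr::all_of(cfg$chain$events))
  )
  new_study_sample(rows, "rct", cfg2, seed)
}

#' @rdname study_designs
#' @export
design_cohort <- function(cfg, n, seed = cfg$seed) {
  pop <- sample_population(cfg, n, seed = seed)
  rows <- dplyr::bind_cols(
    measured_covariates(pop, cfg),
    dplyr::select(pop, "vaccinated", dplyr::all_of(cfg$chain$events))
  )
  new_study_sample(rows, "cohort", cfg, seed)
}

#' @rdname study_designs
#' @export
design_contact_tracing <- function(cfg, n, selection_rule = NULL,
                                   seed = cfg$seed) {
  pop <- sample_population(cfg, n, seed = seed)
  pop <- dplyr::filter(pop, .data$exposed == 1)
  if (!nrow(pop)) {
    abort("no exposed individuals in the scenario; cannot trace contacts",
          class = "vesimlab_empty_sample_error")
  }
  rows <- dplyr::bind_cols(
    measured_covariates(pop, cfg),
    dplyr::select(pop, "vaccinated", "exposed", "variant_measured",
                  dplyr::all_of(cfg$chain$events))
  )
  rows <- apply_selection(rows, selection_rule,
                          derive_seed(seed, "selection"))
  new_study_sample(rows, "contact_tracing", cfg, seed,
                   selection = if (is.null(selection_rule)) "uniform"
                               else "weighted")
}

#' @rdname study_designs
#' @export
design_progression_study <- function(cfg, n, ascertainment_event = "S",
                                     selection_rule = NULL, seed = cfg$seed) {
  ev <- cfg$chain$events
  if (!ascertainment_event %in% ev) {
    abort(sprintf("unknown ascertainment event '%s' (chain events: %s)",
                  ascertainment_event, paste(ev, collapse = ", ")),
          class = "vesimlab_validation_error")
  }
  pop <- sample_population(cfg, n, seed = seed)
  pop <- pop[pop[[ascertainment_event]] == 1, ]
  if (!nrow(pop)) {
    abort(sprintf("no individuals with %s = 1; cannot ascertain",
                  ascertainment_event),
          class = "vesimlab_empty_sample_error")
  }
  downstream <- ev[seq(match(ascertainment_event, ev), length(ev))]
  rows <- dplyr::bind_cols(
    measured_covariates(pop, cfg),
    dplyr::select(pop, "vaccinated", "variant_measured",
                  dplyr::all_of(downstream))
  )
  rows <- apply_selection(rows, selection_rule,
                          derive_seed(seed, "selection"))
  new_study_sample(rows, "progression_study", cfg, seed,
                   ascertainment_event = ascertainment_event,
                   selection = if (is.null(selection_rule)) "uniform"
                               else "weighted")
}

apply_selection <- function(rows, selection_rule, seed) {
  if (is.null(selection_rule)) return(rows)
  w <- selection_rule(rows)
  stopifnot(length(w) == nrow(rows), all(w >= 0))
  set.seed(seed)
  keep <- runif(nrow(rows)) < w / max(w)
  rows[keep, , drop = FALSE]
}

#' Synthesize a severity pyramid from level-specific studies
#'
#' Severity-pyramid analyses estimate the conditional risk of each level of
#' disease severity from a *different* study (one ascertained at symptoms
#' reporting hospitalization risk, one ascertained at hospitalization
#' reporting death risk) and multiply the levels, e.g.
#' `sCFR = r_D|H * r_H|S`. The product equals the directly estimated
#' composite risk only when an individual who clears a level in one study
#' is exchangeable with an individual entering the next level in the other
#' study; this function records the provenance of each level so violations
#' can be demonstrated.
#'
#' @param components List of `study_sample` objects, each ascertained at one
#'   pyramid level (its `ascertainment_event` attribute), covering the
#'   levels in order with no gaps or overlaps.
#' @param chain The [event_chain()] (used to check, via [scfr_compose()],
#'   that the composite has its intended meaning when the levels are
#'   S, H, M).
#' @param levels Ordered character vector of pyramid levels; component `i`
#'   must be ascertained at `levels[i]` and reports the conditional risk of
#'   `levels[i + 1]`.
#' @return A tibble of class `severity_pyramid_tbl` with one row per level
#'   (`from`, `to`, `risk`, `n`, `design`) and the composed product in
#'   `attr(, "composite")`.
#' @export
severity_pyramid <- function(components, chain = default_scenario_chain(),
                             levels = c("S", "H", "M")) {
  asc <- vapply(components, function(s) attr(s, "ascertainment_event"),
                character(1))
  need <- levels[-length(levels)]
  if (!identical(sort(asc), sort(need)) || anyDuplicated(asc)) {
    abort(sprintf(
      "pyramid needs exactly one component per level %s; got components ascertained at: %s",
      paste(need, collapse = ", "), paste(asc, collapse = ", ")),
      class = "vesimlab_composition_error")
  }
  components <- components[match(need, asc)]
  rows <- purrr::map2(components, seq_along(need), function(s, i) {
    to <- levels[i + 1]
    if (!to %in% names(s)) {
      abort(sprintf("component ascertained at %s does not observe %s",
                    need[i], to), class = "vesimlab_composition_error")
    }
    tibble::tibble(from = need[i], to = to,
                   risk = mean(s[[to]]), n = nrow(s),
                   design = attr(s, "design"))
  }) |> dplyr::bind_rows()
  composite <- if (identical(levels, c("S", "H", "M"))) {
    scfr_compose(rows$risk[rows$from == "H"], rows$risk[rows$from == "S"],
                 chain = chain)
  } else {
    prod(rows$risk)
  }
  attr(rows, "composite") <- composite
  attr(rows, "levels") <- levels
  class(rows) <- c("severity_pyramid_tbl", class(rows))
  rows
}
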