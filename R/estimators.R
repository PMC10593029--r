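#' Risk-ratio vaccine-effectiveness estimator
#'
#' Estimates `VE = 1 - RR` for a chosen outcome event from the visible rows
#' of a study sample. Without strata this is the crude risk ratio. With
#' strata, within-stratum risk ratios are combined by standardization to
#' the sample's stratum distribution (a marginal, population-averaged VE);
#' per-stratum results are kept alongside. Strata with an empty arm or with
#' zero risk in the unvaccinated arm cannot contribute a finite risk ratio
#' and are excluded from standardization, with the excluded count recorded
#' on the result (auditable, never silent).
#'
#' Confidence intervals use the large-sample variance of the log risk
#' ratio; for standardized estimates the variance of each standardized risk
#' is obtained by the delta method over stratum-specific binomial risks.
#'
#' @param sample A `study_sample` (or any data frame with a `vaccinated`
#'   column and a 0/1 outcome column).
#' @param outcome_event Name of the outcome event column (e.g. `"S"`,
#'   `"H"`).
#' @param strata Character vector of covariate columns to stratify on, or
#'   `NULL` for the crude estimate.
#' @param truth Optional true causal VE; when supplied, the result carries
#'   `bias = estimate - truth`.
#' @param conf_level Confidence level (default 0.95).
#' @param estimand Label for the estimand (defaults to
#'   `paste0("VE_", outcome_event)`).
#' @return An object of class `ve_estimate`; see [tidy.ve_estimate()].
#' @export
ve_risk_ratio <- function(sample, outcome_event, strata = NULL, truth = NULL,
                          conf_level = 0.95,
                          estimand = paste0("VE_", outcome_event)) {
  assert_masked(sample)
  if (!outcome_event %in% names(sample)) {
    abort(sprintf("outcome event '%s' is not observed in this sample",
                  outcome_event), class = "vesimlab_estimation_error")
  }
  y <- sample[[outcome_event]]
  a <- sample$vaccinated
  if (!any(a == 1) || !any(a == 0)) {
    abort("sample must contain both vaccination arms",
          class = "vesimlab_estimation_error")
  }

  if (is.null(strata)) {
    cells <- tibble::tibble(n1 = sum(a == 1), n0 = sum(a == 0),
                            r1 = mean(y[a == 1]), r0 = mean(y[a == 0]),
                            n = length(y))
  } else {
    cells <- tibble::as_tibble(sample) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
      dplyr::summarise(
        n1 = sum(.data$vaccinated == 1), n0 = sum(.data$vaccinated == 0),
        r1 = mean(.data[[outcome_event]][.data$vaccinated == 1]),
        r0 = mean(.data[[outcome_event]][.data$vaccinated == 0]),
        n = dplyr::n(), .groups = "drop")
  }
  usable <- cells$n1 > 0 & cells$n0 > 0 & cells$r0 > 0
  excluded <- sum(!usable)
  cells_used <- cells[usable, , drop = FALSE]
  if (!nrow(cells_used)) {
    abort("no stratum has both arms and nonzero unvaccinated risk",
          class = "vesimlab_estimation_error")
  }
  w <- cells_used$n / sum(cells_used$n)
  risk1 <- sum(w * cells_used$r1)
  risk0 <- sum(w * cells_used$r0)
  var1 <- sum(w^2 * cells_used$r1 * (1 - cells_used$r1) / cells_used$n1)
  var0 <- sum(w^2 * cells_used$r0 * (1 - cells_used$r0) / cells_used$n0)
  log_rr <- log(risk1 / risk0)
  se_log_rr <- sqrt(var1 / risk1^2 + var0 / risk0^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- 1 - exp(log_rr)
  by_stratum <- cells_used |>
    dplyr::mutate(ve = 1 - .data$r1 / .data$r0)
  new_ve_estimate(
    estimand = estimand,
    estimate = est,
    se = se_log_rr * exp(log_rr), # delta method on 1 - RR
    ci_low = 1 - exp(log_rr + z * se_log_rr),
    ci_high = 1 - exp(log_rr - z * se_log_rr),
    strata = strata,
    n_effective = sum(cells_used$n),
    excluded_strata = excluded,
    truth = truth,
    by_stratum = by_stratum
  )
}

#' Vaccine effectiveness against progression between events
#'
#' `VE = 1 - RR` of the downstream event among individuals in whom the
#' ascertainment event occurred — the conditional, post-treatment-selected
#' quantity (e.g. `VE_H|S`). Because the conditioning event is a common
#' effect of vaccination and of unmeasured risk factors, the crude version
#' of this estimator is subject to collider bias; stratification on
#' measured confounders of the progression step mitigates it.
#'
#' @inheritParams ve_risk_ratio
#' @param from_event Ascertainment event (must be 1 for all analyzed rows).
#' @param to_event Downstream outcome event.
#' @return A `ve_estimate`.
#' @export
ve_progression <- function(sample, from_event, to_event, strata = NULL,
                           truth = NULL, conf_level = 0.95) {
  assert_masked(sample)
  rows <- if (from_event %in% names(sample)) {
    dplyr::filter(tibble::as_tibble(sample), .data[[from_event]] == 1)
  } else if (identical(attr(sample, "ascertainment_event"), from_event)) {
    tibble::as_tibble(sample)
  } else {
    abort(sprintf("sample neither observes '%s' nor is ascertained at it",
                  from_event), class = "vesimlab_estimation_error")
  }
  ve_risk_ratio(rows, to_event, strata = strata, truth = truth,
                conf_level = conf_level,
                estimand = paste0("VE_", to_event, "|", from_event))
}

#' Conditional progression risk between events
#'
#' Estimates `Pr(to_event = 1 | from_event = 1)` with a binomial (Wilson)
#' confidence interval, optionally stratified.
#'
#' @inheritParams ve_progression
#' @return A `ve_estimate` (estimand `r_<to>|<from>`).
#' @export
progression_risk <- function(sample, from_event, to_event, strata = NULL,
                             truth = NULL, conf_level = 0.95) {
  assert_masked(sample)
  rows <- if (from_event %in% names(sample)) {
    dplyr::filter(tibble::as_tibble(sample), .data[[from_event]] == 1)
  } else if (identical(attr(sample, "ascertainment_event"), from_event)) {
    tibble::as_tibble(sample)
  } else {
    abort(sprintf("sample neither observes '%s' nor is ascertained at it",
                  from_event), class = "vesimlab_estimation_error")
  }
  if (!nrow(rows)) {
    abort(sprintf("no individuals with %s = 1 in the sample", from_event),
          class = "vesimlab_estimation_error")
  }
  by_stratum <- NULL
  if (!is.null(strata)) {
    by_stratum <- rows |>
      dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
      dplyr::summarise(risk = mean(.data[[to_event]]), n = dplyr::n(),
                       .groups = "drop")
  }
  x <- sum(rows[[to_event]])
  n <- nrow(rows)
  ci <- suppressWarnings(
    prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int
  )
  new_ve_estimate(
    estimand = paste0("r_", to_event, "|", from_event),
    estimate = x / n,
    se = sqrt(x / n * (1 - x / n) / n),
    ci_low = ci[1], ci_high = ci[2],
    strata = strata, n_effective = n, excluded_strata = 0L,
    truth = truth, by_stratum = by_stratum
  )
}

new_ve_estimate <- function(estimand, estimate, se, ci_low, ci_high, strata,
                            n_effective, excluded_strata, truth, by_stratum) {
  structure(
    list(estimand = estimand, estimate = estimate, se = se,
         ci_low = ci_low, ci_high = ci_high,
         strata = strata %||% character(),
         n_effective = n_effective, excluded_strata = excluded_strata,
         truth = truth,
         bias = if (!is.null(truth)) estimate - truth else NULL,
         by_stratum = by_stratum),
    class = "ve_estimate"
  )
}

#' @export
print.ve_estimate <- function(x, ...) {
  cat(sprintf("<ve_estimate> %s = %.4f  [%.4f, %.4f]  (n = %d%s)\n",
              x$estimand, x$estimate, x$ci_low, x$ci_high, x$n_effective,
              if (length(x$strata)) {
                paste0(", standardized over ",
                       paste(x$strata, collapse = " x "))
              } else ""))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth = %.4f, bias = %+.4f\n", x$truth, x$bias))
  }
  if (x$excluded_strata > 0) {
    cat(sprintf("  note: %d strata excluded (empty arm or zero unvaccinated risk)\n",
                x$excluded_strata))
  }
  invisible(x)
}

#' Tidy and summarize VE estimates
#'
#' `tidy()` returns the one-row tibble of the point estimate with its
#' interval; `glance()` adds the truth/bias bookkeeping.
#'
#' @param x A `ve_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ve_estimate
#' @export
tidy.ve_estimate <- function(x, ...) {
  tibble::tibble(
    estimand = x$estimand, estimate = x$estimate, std.error = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high,
    strata = paste(x$strata, collapse = ","),
    n_effective = x$n_effective,
    truth = x$truth %||% NA_real_,
    bias = x$bias %||% NA_real_
  )
}

#' @rdname tidy.ve_estimate
#' @method glance ve_estimate
#' @export
glance.ve_estimate <- function(x, ...) {
  tibble::tibble(
    estimand = x$estimand, n_effective = x$n_effective,
    excluded_strata = x$excluded_strata,
    truth_available = !is.null(x$truth)
  )
}

#' Bias report across estimates
#'
#' Aggregates replicated estimates per estimand, attaches the causal truth,
#' and flags estimands whose mean bias exceeds three Monte-Carlo standard
#' errors (the package-wide tolerance convention). Estimands missing from
#' `truths` are reported with an empty bias column, not an error.
#'
#' @param results A list of `ve_estimate` objects or a tidy tibble with
#'   columns `estimand`, `estimate` (and optionally `run`).
#' @param truths Named numeric vector of true causal values per estimand.
#' @return A tibble with one row per estimand: `n_runs`, `mean_estimate`,
#'   `truth`, `bias`, `mc_se`, `flagged`.
#' @export
bias_report <- function(results, truths = numeric()) {
  df <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    purrr::map(results, tidy) |> dplyr::bind_rows()
  }
  if (!"std.error" %in% names(df)) df$std.error <- NA_real_
  if (!"run" %in% names(df)) {
    df <- df |>
      dplyr::group_by(.data$estimand) |>
      dplyr::mutate(run = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  df |>
    dplyr::group_by(.data$estimand) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      mc_se = if (dplyr::n() > 1) {
        stats::sd(.data$estimate) / sqrt(dplyr::n())
      } else {
        mean(.data$std.error)
      },
      .groups = "drop") |>
    dplyr::mutate(
      truth = unname(truths[.data$estimand]),
      bias = .data$mean_estimate - .data$truth,
      flagged = !is.na(.data$bias) & abs(.data$bias) > 3 * .data$mc_se
    )
}
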