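#' Worked example: non-monotone waning of conditional effectiveness
#'
#' Applies the conversion `VE_H|S = 1 - (1 - VE_SH)/(1 - VE_S)` to two
#' bundled pairs of waning VE profiles and renders the result at
#' nearest-percent rounding. In the first example both protections wane at
#' similar rates and the conditional measure falls with time since
#' vaccination (70% to 43%); in the second, protection against symptomatic
#' infection wanes much faster than protection against hospitalization and
#' the conditional measure *rises* (63% to 71%) — the cautionary case for
#' treating `VE_H|S` as an effectiveness that must wane.
#'
#' @param profiles Data frame with columns `example`, `stratum_label`,
#'   `ve_s`, `ve_sh`; defaults to the bundled fixture.
#' @return A tibble with the numeric columns of [ve_waning_table()] plus
#'   percent-rendered columns `ve_s_pct`, `ve_h_given_s_pct`, `ve_sh_pct`.
#' @export
reproduce_table2 <- function(profiles = table2_profiles()) {
  out <- profiles |>
    dplyr::group_by(.data$example) |>
    dplyr::group_modify(~ ve_waning_table(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      ve_s_pct = format_percent(.data$ve_s),
      ve_h_given_s_pct = format_percent(.data$ve_h_given_s),
      ve_sh_pct = format_percent(.data$ve_sh)
    )
  class(out) <- c("ve_waning_tbl", class(out))
  out
}

#' @rdname reproduce_table2
#' @export
table2_profiles <- function() {
  path <- system.file("extdata", "table2_ve_profiles.csv",
                      package = "vesimlab", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Check that exposure factors out of the trial risk ratio
#'
#' In a blinded trial, vaccination is independent of exposure, so one minus
#' the *marginal* risk ratio of a downstream event (computable from trial
#' data, where exposure is unobserved) equals one minus the
#' *exposure-conditional* risk ratio (the causal quantity of interest):
#' exposure factors out of the ratio. This experiment computes both on the
#' same simulated populations — the marginal contrast from the visible
#' arms, the conditional contrast using the simulator's exposure oracle —
#' and reports their difference with a Monte-Carlo standard error over
#' replications. With a behavioural effect of vaccination on exposure the
#' identity fails in the configured direction.
#'
#' @param cfg A [scenario_config()]; vaccination is forced randomized.
#' @param n Individuals per replication.
#' @param replications Number of Monte-Carlo replications.
#' @param event Downstream event compared (default symptomatic infection).
#' @param p_vacc Randomization probability.
#' @param seed Root seed; defaults to `cfg$seed`.
#' @return A list of class `rct_identity_report` with `$replicates` (one
#'   row per replication: `ve_marginal`, `ve_conditional_exposure`, `diff`)
#'   and `$summary` (means, `mc_se` of the difference, and `agrees`,
#'   whether |mean diff| <= 3 MC SE).
#' @export
rct_identity_check <- function(cfg, n = 2e5, replications = 20, event = "S",
                               p_vacc = 0.5, seed = cfg$seed) {
  cfg2 <- cfg
  cfg2$vaccination <- list(mechanism = "randomized", p = p_vacc)
  reps <- purrr::map(seq_len(replications), function(r) {
    pop <- quiet_clips(
      sample_population(cfg2, n, seed = derive_seed(seed,
                                                    paste0("rct-rep-", r)))
    )
    a <- pop$vaccinated
    y <- pop[[event]]
    e <- pop$exposed
    ve_m <- 1 - mean(y[a == 1]) / mean(y[a == 0])
    ve_c <- 1 - mean(y[a == 1 & e == 1]) / mean(y[a == 0 & e == 1])
    tibble::tibble(run = r, ve_marginal = ve_m,
                   ve_conditional_exposure = ve_c, diff = ve_m - ve_c)
  }) |> dplyr::bind_rows()
  mc_se <- stats::sd(reps$diff) / sqrt(replications)
  summary <- tibble::tibble(
    n = n, replications = replications, event = event,
    rr_exposure_vaccinated = cfg$exposure$rr_vaccinated,
    mean_marginal = mean(reps$ve_marginal),
    mean_conditional = mean(reps$ve_conditional_exposure),
    mean_diff = mean(reps$diff),
    mc_se = mc_se,
    agrees = abs(mean(reps$diff)) <= 3 * mc_se
  )
  structure(list(replicates = reps, summary = summary),
            class = "rct_identity_report")
}

#' @export
print.rct_identity_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rct_identity_report> marginal VE %.4f vs exposure-conditional VE %.4f\n  diff %.5f (MC SE %.5f over %d reps): %s\n",
    s$mean_marginal, s$mean_conditional, s$mean_diff, s$mc_se,
    s$replications,
    if (s$agrees) "identity holds (within 3 MC SE)" else
      "identity violated (beyond 3 MC SE)"))
  invisible(x)
}

#' Collider-bias experiment for conditional vaccine effectiveness
#'
#' Over a grid of unmeasured-risk-factor strengths and frailty variances,
#' estimates the crude conditional VE against hospitalization among the
#' symptomatic from a progression study, the stratification-adjusted
#' version (risk factor made measurable), and the benchmark: the value the
#' conversion `1 - (1 - VE_SH)/(1 - VE_S)` takes in the matched scenario
#' with the risk-factor effects switched off (same seed). Conditioning on
#' symptomatic infection — a common effect of vaccination and the latent
#' risk factor — distorts the crude estimate when the vaccine's protection
#' is heterogeneous; in strong configurations the vaccine appears to
#' *increase* hospitalization risk while the benchmark is protective.
#'
#' @param grid Tibble of configurations (see [default_collider_grid()]):
#'   columns `label`, `rr_s`, `rr_h`, `interaction`, `frailty_sd`.
#' @param n Individuals per replication.
#' @param replications Monte-Carlo replications per configuration.
#' @param seed Root seed.
#' @return A tibble of class `collider_report`, one row per configuration:
#'   mean `benchmark`, `crude`, `adjusted`, the paired per-replication
#'   deviations `diff_crude`/`diff_adjusted` with their MC standard errors,
#'   deviation flags at 3 MC SE, and `sign_discordant` (crude negative
#'   while benchmark positive). Per-replication rows are kept in
#'   `attr(, "replicates")`.
#' @export
collider_bias_experiment <- function(grid = default_collider_grid(),
                                     n = 1e5, replications = 20, seed = 1L) {
  reps <- purrr::pmap(grid, function(label, rr_s, rr_h, interaction,
                                     frailty_sd) {
    cfg_conf <- scenario_collider(rr_s = rr_s, rr_h = rr_h,
                                  interaction = interaction,
                                  frailty_sd = frailty_sd,
                                  risk_factor_measured = FALSE)
    cfg_meas <- scenario_collider(rr_s = rr_s, rr_h = rr_h,
                                  interaction = interaction,
                                  frailty_sd = frailty_sd,
                                  risk_factor_measured = TRUE)
    cfg_bench <- scenario_collider(rr_s = 1, rr_h = 1, interaction = 1,
                                   frailty_sd = 0)
    purrr::map(seq_len(replications), function(r) {
      s <- derive_seed(seed, paste0("collider-", label, "-", r))
      quiet_clips({
        bench <- true_estimands(cfg_bench, n, seed = s)
        bench_ve <- bench$value[bench$estimand == "VE_H|S"]
        ps_crude <- design_progression_study(cfg_conf, n, "S", seed = s)
        crude <- ve_progression(ps_crude, "S", "H")$estimate
        ps_adj <- design_progression_study(cfg_meas, n, "S", seed = s)
        adjusted <- ve_progression(ps_adj, "S", "H",
                                   strata = "risk_factor")$estimate
      })
      tibble::tibble(label = label, run = r, benchmark = bench_ve,
                     crude = crude, adjusted = adjusted)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  out <- reps |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      diff_crude = mean(.data$crude - .data$benchmark),
      se_crude = stats::sd(.data$crude - .data$benchmark) /
        sqrt(dplyr::n()),
      diff_adjusted = mean(.data$adjusted - .data$benchmark),
      se_adjusted = stats::sd(.data$adjusted - .data$benchmark) /
        sqrt(dplyr::n()),
      benchmark = mean(.data$benchmark),
      crude = mean(.data$crude),
      adjusted = mean(.data$adjusted),
      .groups = "drop") |>
    dplyr::mutate(
      crude_deviates = abs(.data$diff_crude) > 3 * .data$se_crude,
      adjusted_deviates = abs(.data$diff_adjusted) > 3 * .data$se_adjusted,
      sign_discordant = .data$crude < 0 & .data$benchmark > 0
    )
  out <- dplyr::left_join(grid, out, by = "label")
  attr(out, "replicates") <- reps
  class(out) <- c("collider_report", class(out))
  out
}

#' Residual confounding versus measurement quality of the risk factor
#'
#' Stratified adjustment only removes the collider distortion to the extent
#' the stratifying variable is measured correctly. This sweep re-measures
#' the latent risk factor with symmetric accuracy `quality` (sensitivity =
#' specificity), stratifies the conditional VE on the noisy copy, and
#' reports the absolute gap to the benchmark: the gap shrinks as quality
#' rises.
#'
#' @param qualities Vector of measurement accuracies in `(0.5, 1]`.
#' @param n Individuals per replication.
#' @param replications Monte-Carlo replications per quality.
#' @param seed Root seed.
#' @param ... Passed to [scenario_collider()].
#' @return A tibble: `quality`, `adjusted`, `benchmark`, `abs_gap`, `mc_se`.
#' @export
collider_measurement_sweep <- function(qualities = c(0.6, 0.8, 1.0),
                                       n = 1e5, replications = 10,
                                       seed = 1L, ...) {
  cfg <- scenario_collider(risk_factor_measured = TRUE, ...)
  cfg_bench <- scenario_collider(rr_s = 1, rr_h = 1, interaction = 1,
                                 frailty_sd = 0)
  purrr::map(qualities, function(q) {
    gaps <- purrr::map_dbl(seq_len(replications), function(r) {
      s <- derive_seed(seed, paste0("sweep-", q, "-", r))
      bench <- true_estimands(cfg_bench, n, seed = s)
      bench_ve <- bench$value[bench$estimand == "VE_H|S"]
      ps <- design_progression_study(cfg, n, "S", seed = s)
      set.seed(derive_seed(s, "risk-factor-measurement"))
      flip <- runif(nrow(ps)) > q
      ps$risk_factor_noisy <- ifelse(flip, 1L - ps$risk_factor,
                                     ps$risk_factor)
      est <- ve_progression(ps, "S", "H", strata = "risk_factor_noisy")
      est$estimate - bench_ve
    })
    tibble::tibble(quality = q, abs_gap = abs(mean(gaps)),
                   mc_se = stats::sd(gaps) / sqrt(replications))
  }) |> dplyr::bind_rows()
}

#' Exchangeability stress test for severity-pyramid synthesis
#'
#' Composes the symptomatic case-fatality ratio `sCFR = r_D|H * r_H|S` from
#' two level studies and compares it with the direct estimate from a single
#' full-chain sample. With both level studies drawn from the same
#' population (exchangeable selection) the composition agrees with the
#' direct estimate; when the hospitalization-level study over-samples older
#' patients the composed sCFR deviates in the direction of the configured
#' age gradient on death risk (upward).
#'
#' @param cfg Scenario used for all component studies; needs a positive
#'   age gradient on death risk for the mismatched arm to deviate upward.
#' @param n Individuals per component study.
#' @param replications Monte-Carlo replications.
#' @param seed Root seed.
#' @return A tibble of class `pyramid_report`: one row per arm
#'   (`matched`, `mismatched`) with mean `composed`, `direct`, `diff`,
#'   `mc_se`, and `deviates` at 3 MC SE.
#' @export
pyramid_exchangeability_experiment <- function(cfg = scenario_no_bias(),
                                               n = 1e5, replications = 10,
                                               seed = 1L) {
  favor_old <- function(rows) ifelse(rows$age_group == "65+", 1, 0.15)
  one_arm <- function(arm, rule) {
    purrr::map(seq_len(replications), function(r) {
      s1 <- derive_seed(seed, paste0("pyr-", arm, "-S-", r))
      s2 <- derive_seed(seed, paste0("pyr-", arm, "-H-", r))
      s3 <- derive_seed(seed, paste0("pyr-", arm, "-direct-", r))
      comp_s <- design_progression_study(cfg, n, "S", seed = s1)
      comp_h <- design_progression_study(cfg, n, "H", seed = s2,
                                         selection_rule = rule)
      pyr <- severity_pyramid(list(comp_s, comp_h), chain = cfg$chain)
      direct_sample <- design_progression_study(cfg, n, "S", seed = s3)
      direct <- mean(direct_sample$M)
      tibble::tibble(arm = arm, run = r,
                     composed = attr(pyr, "composite"), direct = direct)
    }) |> dplyr::bind_rows()
  }
  reps <- dplyr::bind_rows(one_arm("matched", NULL),
                           one_arm("mismatched", favor_old))
  out <- reps |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      diff = mean(.data$composed - .data$direct),
      mc_se = stats::sd(.data$composed - .data$direct) / sqrt(dplyr::n()),
      composed = mean(.data$composed), direct = mean(.data$direct),
      .groups = "drop") |>
    dplyr::mutate(deviates = abs(.data$diff) > 3 * .data$mc_se)
  attr(out, "replicates") <- reps
  class(out) <- c("pyramid_report", class(out))
  out
}

#' Write the bundled fixture set
#'
#' Writes the waning VE profiles, three canonical scenario configurations
#' (null, confounded, frailty + misclassification) and three small
#' pre-simulated populations (n = 1000) into a directory. Output is
#' byte-identical for a fixed seed.
#'
#' @param out_dir Directory (created if missing).
#' @param seed Root seed for the pre-simulated populations.
#' @return Invisibly, the vector of files written.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(p) files <<- c(files, p)

  p <- file.path(out_dir, "table2_ve_profiles.csv")
  utils::write.csv(table2_profiles(), p, row.names = FALSE)
  add(p)

  cfgs <- list(null = scenario_null(seed),
               confounded = scenario_confounded(seed),
               frailty_misclass = scenario_frailty_misclass(seed = seed))
  for (nm in names(cfgs)) {
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    write_scenario(cfgs[[nm]], p)
    add(p)
    pop <- suppressWarnings(sample_population(cfgs[[nm]], 1000, seed = seed))
    p <- file.path(out_dir, paste0("pop_", nm, ".csv"))
    utils::write.csv(as.data.frame(pop), p, row.names = FALSE)
    add(p)
  }
  invisible(files)
}

# frailty configurations clip a small share of risk products by design;
# inside packaged experiments the per-population warning is muffled (the
# count stays available on each population's attribute)
quiet_clips <- function(expr) {
  withCallingHandlers(
    expr,
    vesimlab_clip_warning = function(w) invokeRestart("muffleWarning")
  )
}
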