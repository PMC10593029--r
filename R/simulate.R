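#' Simulate a population with potential outcomes under both vaccination arms
#'
#' Draws `n` individuals from the structural causal model described by a
#' [scenario_config()]. Each individual carries covariates, a frailty, an
#' observed vaccination status, exposure and variant, and *two* complete
#' outcome vectors: the post-exposure fate had they been unvaccinated and
#' had they been vaccinated. The two arms share all underlying randomness
#' (one uniform draw per individual per event, plus one for exposure), so
#' individual-level potential outcomes are well defined and arm contrasts
#' carry no independent noise. The observed outcome is, by consistency, the
#' potential outcome of the observed arm.
#'
#' @param cfg A [scenario_config()].
#' @param n Number of individuals (>= 1).
#' @param seed Root seed; defaults to `cfg$seed`.
#' @return A tibble of class `sim_population`, one row per individual:
#'   covariates, `frailty`, `vaccinated`, `exposed` (and per-arm
#'   `exposed_a0`/`exposed_a1`), `variant` (NA when unexposed), the
#'   potential outcome columns `<event>_a0` / `<event>_a1`, the observed
#'   event columns, and measured (possibly misclassified) copies
#'   `variant_measured`, `immunocompromised_measured`. The number of risk
#'   products clipped to 1 is in `attr(pop, "clip_count")` (a warning is
#'   raised when positive).
#' @export
sample_population <- function(cfg, n, seed = cfg$seed) {
  stopifnot(n >= 1)
  validate_scenario(cfg)
  ev <- cfg$chain$events
  K <- length(ev)

  l <- draw_covariates(cfg, n, derive_seed(seed, "covariates"))

  set.seed(derive_seed(seed, "frailty"))
  frailty <- if (cfg$frailty_sd > 0) {
    rlnorm(n, meanlog = -cfg$frailty_sd^2 / 2, sdlog = cfg$frailty_sd)
  } else {
    rep(1, n)
  }

  set.seed(derive_seed(seed, "vaccination"))
  vaccinated <- draw_vaccination(cfg, l, n)

  set.seed(derive_seed(seed, "exposure"))
  u_exp <- runif(n)
  p_exp0 <- min(1, cfg$exposure$p)
  p_exp1 <- min(1, cfg$exposure$p * cfg$exposure$rr_vaccinated)
  exposed_a0 <- u_exp < p_exp0
  exposed_a1 <- u_exp < p_exp1

  set.seed(derive_seed(seed, "variant"))
  variant <- draw_variant(cfg, l$calendar_time, n)

  # arm-independent multiplicative factor per (individual, event)
  fac <- matrix(frailty, nrow = n, ncol = K, dimnames = list(NULL, ev))
  for (mod in cfg$risk$modifiers) {
    x <- if (mod$field == "variant") variant else l[[mod$field]]
    if (is.list(mod$rr)) {
      rrm <- do.call(rbind, lapply(mod$rr, align_events, ev = ev))
      idx <- match(as.character(x), names(mod$rr))
      idx[is.na(idx)] <- 1L # unexposed have no variant; factor is irrelevant
      fac <- fac * rrm[idx, , drop = FALSE]
    } else {
      rrv <- align_events(mod$rr, ev)
      fac <- fac * matrix(rep(rrv, each = n), nrow = n)^as.numeric(x)
    }
  }

  set.seed(derive_seed(seed, "events"))
  U <- matrix(runif(n * K), nrow = n, dimnames = list(NULL, ev))

  clip <- 0L
  run_arm <- function(a, exposed_arm) {
    out <- matrix(0L, nrow = n, ncol = K, dimnames = list(NULL, ev))
    vfac <- rep(1, n)
    base <- cfg$risk$baseline[ev]
    rrv <- align_events(cfg$risk$rr_vaccination, ev)
    inter <- cfg$risk$vacc_interaction
    for (k in seq_len(K)) {
      prereq <- cfg$chain$requires[
        cfg$chain$requires[, "event"] == ev[k], "prerequisite"]
      ok <- exposed_arm
      for (pr in prereq) ok <- ok & (out[, pr] == 1L)
      p <- base[k] * fac[, k]
      if (a == 1) {
        p <- p * rrv[k]
        if (!is.null(inter)) {
          p <- p * align_events(inter$rr, ev)[k]^as.numeric(l[[inter$field]])
        }
      }
      clip <<- clip + sum(ok & p > 1)
      p <- pmin(p, 1)
      out[, k] <- as.integer(ok & U[, k] < p)
    }
    out
  }
  out0 <- run_arm(0, exposed_a0)
  out1 <- run_arm(1, exposed_a1)

  obs <- out0
  obs[vaccinated == 1, ] <- out1[vaccinated == 1, ]
  exposed <- ifelse(vaccinated == 1, exposed_a1, exposed_a0)

  pop <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(n)),
    tibble::as_tibble(l),
    tibble::tibble(
      frailty = frailty,
      vaccinated = as.integer(vaccinated),
      exposed_a0 = as.integer(exposed_a0),
      exposed_a1 = as.integer(exposed_a1),
      exposed = as.integer(exposed),
      variant = ifelse(exposed == 1, variant, NA_character_),
      variant_latent = variant
    ),
    tibble::as_tibble(out0) |> dplyr::rename_with(~ paste0(.x, "_a0")),
    tibble::as_tibble(out1) |> dplyr::rename_with(~ paste0(.x, "_a1")),
    tibble::as_tibble(obs)
  )
  pop <- apply_misclassification(pop, cfg, seed = seed)
  attr(pop, "clip_count") <- clip
  attr(pop, "config") <- cfg
  attr(pop, "seed") <- seed
  class(pop) <- c("sim_population", class(pop))
  if (clip > 0) {
    warn(sprintf("%d risk products clipped to 1 during simulation", clip),
         class = "vesimlab_clip_warning")
  }
  pop
}

align_events <- function(x, ev) {
  out <- rep(1, length(ev))
  names(out) <- ev
  out[names(x)[names(x) %in% ev]] <- x[names(x) %in% ev]
  out
}

draw_covariates <- function(cfg, n, seed) {
  set.seed(seed)
  out <- lapply(names(cfg$covariates), function(nm) {
    law <- cfg$covariates[[nm]]
    switch(law$type,
      categorical = sample(law$levels, n, replace = TRUE, prob = law$probs),
      bernoulli = rbinom(n, 1, law$p),
      poisson = rpois(n, law$lambda)
    )
  })
  names(out) <- names(cfg$covariates)
  tibble::as_tibble(out)
}

draw_vaccination <- function(cfg, l, n) {
  v <- cfg$vaccination
  if (v$mechanism == "randomized") {
    return(rbinom(n, 1, v$p))
  }
  lp <- rep(v$intercept %||% 0, n)
  for (nm in names(v$coef %||% list())) {
    co <- v$coef[[nm]]
    x <- l[[nm]]
    lp <- lp + if (!is.null(names(co)) && length(co) > 1) {
      as.numeric(co[as.character(x)])
    } else {
      as.numeric(co) * as.numeric(x)
    }
  }
  rbinom(n, 1, stats::plogis(lp))
}

draw_variant <- function(cfg, calendar_time, n) {
  variants <- cfg$exposure$variants
  u <- runif(n)
  out <- character(n)
  for (pd in unique(calendar_time)) {
    mix <- cfg$exposure$mixture[[as.character(pd)]][variants]
    cum <- cumsum(mix)
    sel <- calendar_time == pd
    out[sel] <- variants[findInterval(u[sel], c(0, cum),
                                      rightmost.closed = TRUE)]
  }
  out
}

#' Apply measurement error to variant and immunocompromised status
#'
#' Overwrites the `variant_measured` and `immunocompromised_measured`
#' columns with Bernoulli-flipped copies of the true values, per the
#' configured sensitivity and specificity. The variant call is binary in
#' the style of an S-gene-target-failure proxy: the last level of
#' `cfg$exposure$variants` is the "positive" call. True columns are never
#' touched; the operation is deterministic given the seed.
#'
#' @param pop A population from [sample_population()].
#' @param cfg The [scenario_config()].
#' @param seed Root seed (child stream `"misclassification"` is used).
#' @return `pop` with refreshed measured columns.
#' @export
apply_misclassification <- function(pop, cfg, seed = cfg$seed) {
  set.seed(derive_seed(seed, "misclassification"))
  n <- nrow(pop)
  mv <- cfg$misclassification$variant
  variants <- cfg$exposure$variants
  pos <- variants[length(variants)]
  neg <- variants[1L]
  true_pos <- !is.na(pop$variant) & pop$variant == pos
  u <- runif(n)
  measured <- rep(NA_character_, n)
  measured[true_pos] <- ifelse(u[true_pos] < mv[["sensitivity"]], pos, neg)
  oth <- !is.na(pop$variant) & !true_pos
  measured[oth] <- ifelse(u[oth] < mv[["specificity"]], pop$variant[oth], pos)
  pop$variant_measured <- measured

  mi <- cfg$misclassification$immunocompromised
  u2 <- runif(n)
  ic <- pop$immunocompromised
  pop$immunocompromised_measured <- as.integer(
    ifelse(ic == 1, u2 < mi[["sensitivity"]], u2 >= mi[["specificity"]])
  )
  pop
}

#' Ground-truth causal estimands of a scenario
#'
#' Computes, from the potential outcomes of a simulated population, the
#' per-arm counterfactual risks of each event among the exposed, the true
#' marginal vaccine effectiveness against symptomatic infection (`VE_S`)
#' and against hospitalization (`VE_SH`), and the conditional `VE_H|S`
#' implied by the conversion `1 - (1 - VE_SH)/(1 - VE_S)`. Because both
#' potential outcomes are available for every individual, these are causal
#' quantities, not estimates subject to design bias.
#'
#' @param cfg A [scenario_config()].
#' @param n Population size used for the Monte-Carlo evaluation.
#' @param seed Root seed; defaults to `cfg$seed`.
#' @param by Optional character vector of covariate columns; when given,
#'   estimands are also returned within each stratum.
#' @param pop Optionally, an existing population from [sample_population()]
#'   (then `cfg`, `n`, `seed` are ignored for generation).
#' @return A tibble with columns `estimand`, stratum columns (if `by`),
#'   and `value`.
#' @export
true_estimands <- function(cfg, n = 1e5, seed = cfg$seed, by = NULL,
                           pop = NULL) {
  if (is.null(pop)) pop <- sample_population(cfg, n, seed = seed)
  cfg <- attr(pop, "config")
  ev <- cfg$chain$events
  one <- function(df) {
    e0 <- df$exposed_a0 == 1
    e1 <- df$exposed_a1 == 1
    risks <- purrr::map(ev, function(k) {
      tibble::tibble(
        estimand = c(paste0("risk_", k, "_a0"), paste0("risk_", k, "_a1")),
        value = c(mean(df[[paste0(k, "_a0")]][e0]),
                  mean(df[[paste0(k, "_a1")]][e1]))
      )
    }) |> dplyr::bind_rows()
    rr <- function(k) {
      r0 <- risks$value[risks$estimand == paste0("risk_", k, "_a0")]
      r1 <- risks$value[risks$estimand == paste0("risk_", k, "_a1")]
      r1 / r0
    }
    ve_s <- 1 - rr("S")
    ve_sh <- 1 - rr("H")
    ve_hs <- if (is.finite(ve_s) && is.finite(ve_sh) && ve_s < 1) {
      ve_conditional(ve_s, ve_sh)
    } else {
      NA_real_ # degenerate scenario: a VE denominator risk is zero
    }
    dplyr::bind_rows(
      risks,
      tibble::tibble(estimand = c("VE_S", "VE_SH", "VE_H|S"),
                     value = c(ve_s, ve_sh, ve_hs))
    )
  }
  if (is.null(by)) {
    one(pop)
  } else {
    pop |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  }
}
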