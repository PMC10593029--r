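test_that("degenerate exposure configurations produce the determined outcomes", {
  cfg0 <- plain_scenario(p_exposure = 0)
  pop <- sample_population(cfg0, 300)
  ev_cols <- c(paste0(cfg0$chain$events, "_a0"),
               paste0(cfg0$chain$events, "_a1"), cfg0$chain$events)
  expect_true(all(as.matrix(pop[, ev_cols]) == 0))

  cfg1 <- plain_scenario(p_exposure = 1, p_i = 1, p_s = 0)
  pop1 <- sample_population(cfg1, 300)
  expect_true(all(pop1$I == 1))
  expect_true(all(as.matrix(pop1[, c("S", "D", "H", "C", "M")]) == 0))
})

test_that("populations are reproducible and seed-sensitive", {
  cfg <- scenario_no_bias(seed = 3L)
  a <- sample_population(cfg, 2000)
  b <- sample_population(cfg, 2000)
  expect_identical(pop_data(a), pop_data(b))
  c <- sample_population(cfg, 2000, seed = 4L)
  expect_false(identical(pop_data(a), pop_data(c)))
})

test_that("consistency and feasibility hold for every simulated individual", {
  cfg <- scenario_frailty_misclass(seed = 12L)
  pop <- suppressWarnings(sample_population(cfg, 5000))
  ev <- cfg$chain$events
  po <- as.matrix(pop[, paste0(ev, "_a0")])
  v <- pop$vaccinated == 1
  po[v, ] <- as.matrix(pop[v, paste0(ev, "_a1")])
  expect_identical(unname(as.matrix(pop[, ev])), unname(po))
  expect_true(all(is_feasible(pop[, ev], cfg$chain)))
  expect_true(all(is_feasible(setNames(pop[, paste0(ev, "_a0")], ev),
                              cfg$chain)))
  expect_true(all(is_feasible(setNames(pop[, paste0(ev, "_a1")], ev),
                              cfg$chain)))
  # unexposed individuals never experience any event
  unexp <- pop$exposed == 0
  expect_true(all(as.matrix(pop[unexp, ev]) == 0))
})

test_that("randomized vaccination with no behavioural pathway balances exposure", {
  cfg <- scenario_no_bias(seed = 21L)
  pop <- sample_population(cfg, 1e5)
  p1 <- mean(pop$exposed[pop$vaccinated == 1])
  p0 <- mean(pop$exposed[pop$vaccinated == 0])
  se <- sqrt(p0 * (1 - p0) * (1 / sum(pop$vaccinated == 1) +
                                1 / sum(pop$vaccinated == 0)))
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("empirical conditional risks recover the configured risk model", {
  cfg <- plain_scenario(p_exposure = 0.5, p_i = 0.5, p_s = 0.6,
                        rr_i = 0.7, rr_s = 0.5, seed = 31L)
  pop <- sample_population(cfg, 2e5)
  tol3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  unv <- pop$vaccinated == 0 & pop$exposed_a0 == 1
  vac <- pop$vaccinated == 1 & pop$exposed_a1 == 1
  expect_lt(abs(mean(pop$I[unv]) - 0.5), tol3(0.5, sum(unv)))
  expect_lt(abs(mean(pop$I[vac]) - 0.5 * 0.7), tol3(0.35, sum(vac)))
  s_unv <- unv & pop$I == 1
  s_vac <- vac & pop$I == 1
  expect_lt(abs(mean(pop$S[s_unv]) - 0.6), tol3(0.6, sum(s_unv)))
  expect_lt(abs(mean(pop$S[s_vac]) - 0.6 * 0.5), tol3(0.3, sum(s_vac)))
})

test_that("a strong symptom multiplier is recovered as 1 - RR among the exposed", {
  cfg <- plain_scenario(p_exposure = 1, p_i = 1, p_s = 0.5,
                        rr_i = 1, rr_s = 0.1, seed = 55L)
  pop <- sample_population(cfg, 2e5)
  te <- true_estimands(cfg, pop = pop)
  ve_s <- te$value[te$estimand == "VE_S"]
  expect_lt(abs(ve_s - 0.9), 0.02)
})

test_that("true estimands satisfy the composition identity and vanish under the null", {
  cfg <- scenario_null(seed = 17L)
  te <- true_estimands(cfg, 2e4)
  # common random numbers: under the null both arms are bit-identical
  expect_equal(te$value[te$estimand == "VE_S"], 0, tolerance = 1e-12)
  expect_equal(te$value[te$estimand == "VE_SH"], 0, tolerance = 1e-12)

  cfg2 <- scenario_no_bias(seed = 18L)
  te2 <- true_estimands(cfg2, 5e4)
  ve_s <- te2$value[te2$estimand == "VE_S"]
  ve_sh <- te2$value[te2$estimand == "VE_SH"]
  ve_hs <- te2$value[te2$estimand == "VE_H|S"]
  expect_equal(ve_compose(ve_s, ve_hs), ve_sh, tolerance = 1e-12)
})

test_that("a pure symptom effect leaves the conditional VE near zero", {
  cfg <- plain_scenario(p_exposure = 1, p_i = 1, p_s = 0.5,
                        rr_i = 1, rr_s = 0.1, seed = 77L)
  cfg$risk$baseline[c("D", "H")] <- c(0.8, 0.3)
  te <- true_estimands(cfg, 2e5)
  ve_hs <- te$value[te$estimand == "VE_H|S"]
  expect_lt(abs(ve_hs), 0.1)
})

test_that("misclassification follows the configured confusion rates", {
  cfg <- scenario_no_bias(seed = 41L)
  pop <- sample_population(cfg, 5e4)
  expect_identical(pop$immunocompromised_measured, pop$immunocompromised)
  expect_identical(pop$variant_measured, pop$variant)

  cfg$misclassification$immunocompromised <- c(sensitivity = 1,
                                               specificity = 0)
  pop2 <- apply_misclassification(pop, cfg, seed = 41L)
  expect_true(all(pop2$immunocompromised_measured == 1))

  cfg$misclassification$immunocompromised <- c(sensitivity = 0.9,
                                               specificity = 0.95)
  pop3 <- apply_misclassification(pop, cfg, seed = 42L)
  pos <- pop3$immunocompromised == 1
  sens_hat <- mean(pop3$immunocompromised_measured[pos])
  spec_hat <- mean(1 - pop3$immunocompromised_measured[!pos])
  expect_lt(abs(sens_hat - 0.9), 3 * sqrt(0.9 * 0.1 / sum(pos)))
  expect_lt(abs(spec_hat - 0.95), 3 * sqrt(0.95 * 0.05 / sum(!pos)))
})

test_that("invalid configurations are rejected with the offending fields named", {
  cfg <- scenario_no_bias()
  cfg$exposure$p <- 1.4
  cfg$covariates$prior_infection$p <- -0.1
  err <- tryCatch(validate_scenario(cfg), error = function(e) e)
  expect_s3_class(err, "vesimlab_validation_error")
  expect_match(conditionMessage(err), "exposure\\$p")
  expect_match(conditionMessage(err), "prior_infection")
})

test_that("risk clipping is counted and reported", {
  cfg <- plain_scenario(p_exposure = 1, p_i = 0.9, p_s = 0.5, seed = 9L)
  cfg$frailty_sd <- 1.5 # large frailty forces products above 1
  expect_warning(pop <- sample_population(cfg, 5000),
                 class = "vesimlab_clip_warning")
  expect_gt(attr(pop, "clip_count"), 0)
  pop0 <- sample_population(scenario_no_bias(seed = 9L), 5000)
  expect_identical(attr(pop0, "clip_count"), 0L)
})

test_that("scenario configurations round-trip through YAML and JSON", {
  cfg <- scenario_confounded(seed = 14L)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(cfg, path)
    back <- read_scenario(path)
    a <- sample_population(cfg, 1000)
    b <- sample_population(back, 1000)
    expect_identical(pop_data(a), pop_data(b))
  }
})
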