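test_that("study samples never expose counterfactual or latent columns", {
  cfg <- scenario_no_bias(seed = 5L)
  for (s in list(design_challenge_trial(cfg, 2000),
                 design_rct(cfg, 2000),
                 design_cohort(cfg, 2000),
                 design_contact_tracing(cfg, 2000),
                 design_progression_study(cfg, 5000, "S"))) {
    expect_length(grep("_a[01]$|frailty", names(s)), 0)
  }
  leaky <- tibble::tibble(vaccinated = c(0, 1), S = c(1, 0), S_a0 = c(1, 1))
  expect_error(assert_masked(leaky), class = "vesimlab_masking_error")
  expect_error(ve_risk_ratio(leaky, "S"), class = "vesimlab_masking_error")
})

test_that("challenge trials expose everyone and recover the true VE", {
  cfg <- scenario_null(seed = 101L)
  s <- design_challenge_trial(cfg, 3e4)
  expect_true(all(s$exposed == 1))
  est <- ve_risk_ratio(s, "S")
  expect_lt(abs(est$estimate), 3 * est$se)

  cfg2 <- scenario_no_bias(seed = 102L)
  te <- true_estimands(cfg2, pop = {
    c3 <- cfg2; c3$exposure$p <- 1
    c3$exposure$mixture <- lapply(c3$exposure$mixture,
                                  function(m) c(delta = 1, omicron = 0))
    sample_population(c3, 1e5, seed = 555L)
  })
  s2 <- design_challenge_trial(cfg2, 1e5, variant = "delta", seed = 556L)
  est2 <- ve_risk_ratio(s2, "S")
  expect_lt(abs(est2$estimate - te$value[te$estimand == "VE_S"]),
            3 * est2$se)
})

test_that("the RCT emulator hides exposure and refuses unblinded scenarios", {
  cfg <- scenario_no_bias(seed = 7L)
  s <- design_rct(cfg, 5000)
  expect_false("exposed" %in% names(s))
  expect_false("variant_measured" %in% names(s))
  cfg$exposure$rr_vaccinated <- 1.3
  expect_error(design_rct(cfg, 1000), class = "vesimlab_design_error")

  cfg0 <- scenario_no_bias(seed = 8L)
  cfg0$exposure$p <- 0
  s0 <- design_rct(cfg0, 2000)
  expect_equal(sum(s0$S), 0)
})

test_that("cohorts match trials absent confounding and reveal it when present", {
  cfg <- scenario_no_bias(seed = 61L) # randomized mechanism: no confounding
  rct <- design_rct(cfg, 1.5e5)
  coh <- design_cohort(cfg, 1.5e5, seed = 62L)
  e_r <- ve_risk_ratio(rct, "S")
  e_c <- ve_risk_ratio(coh, "S")
  expect_lt(abs(e_r$estimate - e_c$estimate),
            3 * sqrt(e_r$se^2 + e_c$se^2))

  cfgc <- scenario_confounded(seed = 63L)
  te <- true_estimands(cfgc, 3e5, seed = 99L)
  truth <- te$value[te$estimand == "VE_SH"]
  coh2 <- design_cohort(cfgc, 3e5)
  crude <- ve_risk_ratio(coh2, "H", truth = truth)
  adj <- ve_risk_ratio(coh2, "H", strata = c("age_group", "immunocompromised"),
                       truth = truth)
  expect_gt(abs(crude$bias), 3 * crude$se)   # confounded
  expect_lt(abs(adj$bias), 3 * adj$se)       # stratification closes the path
  expect_lt(crude$estimate, truth)           # uptake skews to the high-risk old
})

test_that("a behavioural exposure pathway biases the cohort against the vaccine", {
  cfg <- scenario_no_bias(seed = 64L)
  cfg$exposure$rr_vaccinated <- 1.4
  te <- true_estimands(cfg, 2e5, seed = 98L)
  truth <- te$value[te$estimand == "VE_S"]
  coh <- design_cohort(cfg, 2e5)
  est <- ve_risk_ratio(coh, "S", truth = truth)
  expect_gt(abs(est$bias), 3 * est$se)
  expect_lt(est$estimate, truth) # more exposure among the vaccinated
})

test_that("contact tracing recovers post-exposure risks and reflects selection", {
  cfg <- scenario_no_bias(seed = 71L)
  s <- design_contact_tracing(cfg, 2e5)
  te <- true_estimands(cfg, 2e5, seed = 71L)
  r0 <- mean(s$S[s$vaccinated == 0])
  truth0 <- te$value[te$estimand == "risk_S_a0"]
  expect_lt(abs(r0 - truth0), 3 * sqrt(truth0 * (1 - truth0) /
                                         sum(s$vaccinated == 0)))

  favor_old <- function(rows) ifelse(rows$age_group == "65+", 1, 0.1)
  s_old <- design_contact_tracing(cfg, 2e5, selection_rule = favor_old)
  # crude hospitalization risk shifts toward the older stratum's risk
  expect_gt(mean(s_old$H[s_old$vaccinated == 0]),
            mean(s$H[s$vaccinated == 0]))
  # within the selected stratum the risk is unchanged by selection
  r_old_sel <- mean(s_old$H[s_old$age_group == "65+" & s_old$vaccinated == 0])
  r_old_all <- mean(s$H[s$age_group == "65+" & s$vaccinated == 0])
  n_sel <- sum(s_old$age_group == "65+" & s_old$vaccinated == 0)
  expect_lt(abs(r_old_sel - r_old_all),
            3 * sqrt(r_old_all * (1 - r_old_all) / n_sel) +
              3 * sqrt(r_old_all * (1 - r_old_all) /
                         sum(s$age_group == "65+" & s$vaccinated == 0)))

  cfg0 <- scenario_no_bias(seed = 72L)
  cfg0$exposure$p <- 0
  expect_error(design_contact_tracing(cfg0, 1000),
               class = "vesimlab_empty_sample_error")
})

test_that("progression studies ascertain correctly and validate their inputs", {
  cfg <- scenario_no_bias(seed = 81L)
  s <- design_progression_study(cfg, 2e4, "S")
  expect_true(all(s$S == 1))
  expect_false("I" %in% names(s)) # upstream of the ascertainment event
  expect_true(all(c("H", "C", "M") %in% names(s)))
  expect_error(design_progression_study(cfg, 1000, "X"),
               class = "vesimlab_validation_error")
  cfg0 <- scenario_no_bias(seed = 82L)
  cfg0$risk$baseline["M"] <- 0
  expect_error(design_progression_study(cfg0, 2000, "M"),
               class = "vesimlab_empty_sample_error")
})

test_that("severity pyramids compose exchangeable components and refuse bad level sets", {
  cfg <- scenario_no_bias(seed = 91L)
  comp_s <- design_progression_study(cfg, 1e5, "S", seed = 911L)
  comp_h <- design_progression_study(cfg, 1e5, "H", seed = 912L)
  pyr <- severity_pyramid(list(comp_s, comp_h), chain = cfg$chain)
  expect_identical(pyr$from, c("S", "H"))
  expect_equal(attr(pyr, "composite"),
               pyr$risk[1] * pyr$risk[2], tolerance = 1e-12)
  # duplicate level
  expect_error(severity_pyramid(list(comp_s, comp_s), chain = cfg$chain),
               class = "vesimlab_composition_error")
  # missing level
  expect_error(severity_pyramid(list(comp_s), chain = cfg$chain),
               class = "vesimlab_composition_error")
  # single component covering the whole span
  solo <- severity_pyramid(list(comp_s), chain = cfg$chain,
                           levels = c("S", "M"))
  expect_equal(attr(solo, "composite"), mean(comp_s$M), tolerance = 1e-12)
})

test_that("pyramid synthesis agrees under exchangeability and deviates under age-biased selection", {
  rep <- pyramid_exchangeability_experiment(cfg = scenario_no_bias(seed = 95L),
                                            n = 1.5e5, replications = 8,
                                            seed = 95L)
  matched <- rep[rep$arm == "matched", ]
  mismatched <- rep[rep$arm == "mismatched", ]
  expect_false(matched$deviates)
  expect_true(mismatched$deviates)
  expect_gt(mismatched$diff, 0) # configured age gradient raises death risk
})

test_that("study samples round-trip through CSV with their JSON sidecar", {
  cfg <- scenario_no_bias(seed = 15L)
  s <- design_progression_study(cfg, 5000, "S")
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_sample(s, path)
  back <- read_study_sample(path)
  expect_identical(attr(back, "design"), "progression_study")
  expect_identical(attr(back, "ascertainment_event"), "S")
  expect_equal(nrow(back), nrow(s))
  expect_equal(mean(back$H), mean(s$H))
})
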