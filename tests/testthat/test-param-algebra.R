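test_that("conditional VE conversion reproduces the worked waning examples", {
  expect_equal(ve_conditional(0.90, 0.97), 0.70, tolerance = 1e-12)
  expect_equal(ve_conditional(0.65, 0.80), 3 / 7, tolerance = 1e-12)
  expect_identical(format_percent(ve_conditional(0.65, 0.80)), "43%")
  expect_identical(format_percent(ve_conditional(0.62, 0.86)), "63%")
  # no protection against infection: conditional equals unconditional
  for (x in c(-0.5, 0, 0.3, 0.71, 1)) {
    expect_equal(ve_conditional(0, x), x, tolerance = 1e-12)
  }
})

test_that("composition inverts the conditional conversion exactly", {
  expect_equal(ve_compose(0.62, 0.63), 0.8594, tolerance = 1e-12)
  expect_identical(format_percent(ve_compose(0.62, 0.63)), "86%")
  expect_equal(ve_compose(0.4, 0), 0.4, tolerance = 1e-12)
  grid <- expand.grid(ve_s = seq(-1, 0.95, by = 0.05),
                      ve_sh = seq(-1, 1, by = 0.1))
  expect_equal(ve_compose(grid$ve_s, ve_conditional(grid$ve_s, grid$ve_sh)),
               grid$ve_sh, tolerance = 1e-12)
  expect_equal(ve_conditional(grid$ve_s, ve_compose(grid$ve_s, grid$ve_sh)),
               grid$ve_sh, tolerance = 1e-12)
})

test_that("conditional VE conversion guards its domain", {
  expect_error(ve_conditional(1, 0.97), class = "vesimlab_domain_error")
  expect_error(ve_conditional(0.5, 1.2), class = "vesimlab_domain_error")
  expect_error(ve_compose(1.5, 0.5), class = "vesimlab_domain_error")
  # negative VE (harm) is a legal input
  expect_equal(ve_conditional(-0.5, 0.25), 0.5, tolerance = 1e-12)
})

test_that("conditional VE is monotone in both arguments", {
  s <- seq(-0.5, 0.9, by = 0.1)
  for (sh in c(0.2, 0.5, 0.9)) {
    expect_true(all(diff(ve_conditional(s, sh)) < 0))
  }
  sh <- seq(-0.5, 0.99, by = 0.1)
  for (ve_s in c(0, 0.5, 0.9)) {
    expect_true(all(diff(ve_conditional(ve_s, sh)) > 0))
  }
})

test_that("sCFR composition requires deaths to pass through hospitalization", {
  expect_equal(scfr_compose(0, 0.7), 0)
  expect_equal(scfr_compose(1, 1), 1)
  skip_chain <- event_chain(requires = list(
    c("I", "S"), c("I", "D"), c("D", "H"), c("H", "C"), c("I", "M")
  ))
  expect_error(scfr_compose(0.2, 0.1, chain = skip_chain),
               class = "vesimlab_decomposition_error")
  # transitive prerequisite (M requires C requires H) is accepted
  trans_chain <- event_chain(requires = list(
    c("I", "S"), c("I", "D"), c("D", "H"), c("H", "C"), c("C", "M")
  ))
  expect_equal(scfr_compose(0.2, 0.1, chain = trans_chain), 0.02)
})

test_that("sCFR composition agrees with direct summation over a joint distribution", {
  chain <- default_scenario_chain() # H requires S and D; M requires H
  set.seed(11)
  mass <- enumerate_feasible(chain)
  mass$prob <- runif(nrow(mass))
  mass$prob <- mass$prob / sum(mass$prob)
  j <- joint_outcome_distribution(mass, chain)
  # direct brute-force conditionals from the joint mass
  p_m_given_s <- sum(j$prob[j$M == 1 & j$S == 1]) / sum(j$prob[j$S == 1])
  r_m_h <- sum(j$prob[j$M == 1 & j$H == 1]) / sum(j$prob[j$H == 1])
  r_h_s <- sum(j$prob[j$H == 1 & j$S == 1]) / sum(j$prob[j$S == 1])
  expect_equal(scfr_compose(r_m_h, r_h_s, chain = chain), p_m_given_s,
               tolerance = 1e-12)
})

test_that("joint-to-conditional flags unreached histories explicitly", {
  chain <- event_chain()
  mass <- enumerate_feasible(chain)
  mass$prob <- as.numeric(rowSums(mass) == 0) # point mass on all-zeros
  t <- joint_to_conditional(joint_outcome_distribution(mass, chain))
  expect_equal(t$prob[t$event == "I"], 0)
  deeper <- t[t$event != "I" & grepl("I=1", t$history), ]
  expect_true(all(!deeper$defined))
  expect_true(all(is.na(deeper$prob)))
})

test_that("uniform strict-chain joint yields the brute-force conditionals", {
  ev <- c("I", "S", "D", "H", "C", "M")
  strict <- event_chain(ev, requires = list(
    c("I", "S"), c("S", "D"), c("D", "H"), c("H", "C"), c("C", "M")
  ))
  mass <- enumerate_feasible(strict)
  mass$prob <- rep(1 / 7, 7)
  t <- joint_to_conditional(joint_outcome_distribution(mass, strict))
  # under uniform mass on the 7 prefix vectors, Pr(next event | k ones so
  # far, all reached) = (6 - k) / (7 - k): brute-force counting
  all_ones_hist <- function(k) {
    if (k == 0) "" else paste0(ev[seq_len(k)], "=1", collapse = ",")
  }
  for (k in 0:5) {
    entry <- t[t$event == ev[k + 1] & t$history == all_ones_hist(k), ]
    expect_equal(entry$prob, (6 - k) / (7 - k), tolerance = 1e-12)
  }
})

test_that("two-event conditional table multiplies out to the stated joint", {
  chain <- event_chain(c("I", "S"), list(c("I", "S")))
  t <- tibble::tibble(
    event = c("I", "S", "S"),
    history = c("", "I=0", "I=1"),
    prob = c(0.5, 0, 0.4),
    defined = TRUE
  )
  j <- conditional_to_joint(t, chain)
  expect_equal(j$prob[j$I == 0 & j$S == 0], 0.5)
  expect_equal(j$prob[j$I == 1 & j$S == 0], 0.3)
  expect_equal(j$prob[j$I == 1 & j$S == 1], 0.2)
})

test_that("joint and conditional representations are mutually inverse", {
  chain <- default_scenario_chain()
  for (seed in c(5, 6, 7)) {
    t <- random_progression_table(chain, seed)
    j <- conditional_to_joint(t, chain)
    expect_equal(sum(j$prob), 1, tolerance = 1e-12)
    t2 <- joint_to_conditional(j)
    expect_equal(t2$prob[t2$defined], t$prob[match(
      paste(t2$event[t2$defined], t2$history[t2$defined]),
      paste(t$event, t$history))], tolerance = 1e-12)
    j2 <- conditional_to_joint(t2, chain)
    expect_equal(j2$prob, j$prob, tolerance = 1e-12)
  }
  # degenerate: all conditionals beyond infection are zero
  set.seed(8)
  mass <- enumerate_feasible(chain)
  mass$prob <- 0
  mass$prob[rowSums(mass[, chain$events]) == 0] <- 0.7
  mass$prob[mass$I == 1 & rowSums(mass[, chain$events]) == 1] <- 0.3
  j <- joint_outcome_distribution(mass, chain)
  j2 <- conditional_to_joint(joint_to_conditional(j), chain)
  expect_equal(j2$prob, j$prob, tolerance = 1e-12)
})

test_that("incomplete progression tables are refused", {
  chain <- event_chain(c("I", "S"), list(c("I", "S")))
  t <- tibble::tibble(event = "I", history = "", prob = 0.5, defined = TRUE)
  expect_error(conditional_to_joint(t, chain),
               class = "vesimlab_incomplete_table_error")
})

test_that("waning tables preserve stratum order and expose non-monotone trends", {
  tbl <- ve_waning_table(data.frame(
    stratum_label = c("Recent", "Longer ago"),
    ve_s = c(0.62, 0.00), ve_sh = c(0.86, 0.71)
  ))
  expect_identical(tbl$stratum_label, c("Recent", "Longer ago"))
  expect_true(tbl$ve_h_given_s[2] > tbl$ve_h_given_s[1]) # increases as VE_S wanes
  same <- ve_waning_table(data.frame(
    stratum_label = c("a", "b"), ve_s = c(0.5, 0.5), ve_sh = c(0.8, 0.8)
  ))
  expect_equal(same$ve_h_given_s[1], same$ve_h_given_s[2])
})
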