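# Independent brute-force oracle for outcome-space enumeration: materialize
# all 2^n binary vectors and filter by checking every precedence pair
# directly (no calls into the package's enumeration path).
brute_force_feasible <- function(events, requires) {
  n <- length(events)
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(m) <- events
  keep <- rep(TRUE, nrow(m))
  for (p in requires) {
    keep <- keep & (m[, p[2]] == 0 | m[, p[1]] == 1)
  }
  m[keep, , drop = FALSE]
}

# canonical string form for order-insensitive set comparison of 0/1 rows
row_patterns <- function(m) {
  sort(apply(as.matrix(m), 1, paste, collapse = ""))
}

# population data stripped of bookkeeping attributes, for bitwise comparison
pop_data <- function(pop) {
  df <- as.data.frame(pop)
  for (a in c("config", "seed", "clip_count", "chain", "provenance",
              "design", "ascertainment_event")) {
    attr(df, a) <- NULL
  }
  df
}

# a minimal two-event scenario with fully controllable risks, no covariate
# effects, used for closed-form checks
plain_scenario <- function(p_exposure = 1, p_i = 0.5, p_s = 0.6,
                           rr_i = 1, rr_s = 1, seed = 1L) {
  risk <- default_risk_model()
  risk$baseline <- c(I = p_i, S = p_s, D = 0, H = 0, C = 0, M = 0)
  risk$rr_vaccination <- c(I = rr_i, S = rr_s, D = 1, H = 1, C = 1, M = 1)
  risk$modifiers <- list()
  scenario_config(
    exposure = list(p = p_exposure, rr_vaccinated = 1,
                    variants = c("delta", "omicron"),
                    mixture = list(`1` = c(delta = 1, omicron = 0),
                                   `2` = c(delta = 1, omicron = 0))),
    risk = risk,
    seed = seed
  )
}

# random full-history progression table over a chain, all entries defined
random_progression_table <- function(chain, seed) {
  set.seed(seed)
  skeleton <- joint_to_conditional(
    joint_outcome_distribution(
      dplyr::mutate(enumerate_feasible(chain),
                    prob = 1 / dplyr::n()),
      chain
    )
  )
  # entries for events whose prerequisites are absent from the history are
  # structurally zero under the uniform joint and must stay zero
  free <- skeleton$prob > 0
  skeleton$prob[free] <- runif(sum(free), min = 0.05, max = 0.95)
  skeleton$defined <- TRUE
  skeleton
}
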