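# vesimlab

A simulation laboratory for studying how epidemiologic study designs
recover — or fail to recover — the causal parameters needed to parameterize
an individual-based infectious-disease transmission model.

Individual-based models need counterfactual probabilities
Pr(event^{e,a} = 1 | L = l) for a chain of post-exposure events (infection
I, symptoms S, diagnosis D, hospitalization H, ICU C, death M), per
covariate stratum L, vaccination arm a and variant e. Real studies estimate
related but different quantities. `vesimlab` provides:

* **Outcome-space algebra** — enumeration of feasible outcome vectors under
  configurable precedence constraints (between n + 1 and 2^n vectors for n
  events), and exact conversion between joint outcome distributions and
  step-by-step progression-probability tables.
* **Effectiveness algebra** — the exact conversion between marginal and
  conditional vaccine effectiveness,

  VE_H|S = 1 − (1 − VE_SH) / (1 − VE_S),

  its inverse, and the severity-pyramid composition sCFR = r_D|H · r_H|S
  (refused when the event chain permits death without hospitalization).
* **A structural-causal-model simulator** — populations with covariates,
  confounded or randomized vaccination, variant mixtures over calendar
  time, misclassification, shared frailty, and per-individual potential
  outcomes under both arms (common random numbers), so every causal
  estimand has computable ground truth.
* **Study-design emulators** — challenge trial, RCT (exposure unobserved),
  cohort, contact tracing, post-exposure progression studies and severity
  pyramids, each observing only what that design could see (counterfactual
  columns are masked; reading them is an error).
* **Estimators and bias bookkeeping** — crude and standardized risk-ratio
  VE, conditional progression risks, and bias reports against ground truth.
* **Packaged experiments** — the worked waning example, the
  exposure-factors-out-of-the-ratio identity check for blinded trials, a
  collider-bias grid in which conditioning on symptoms makes an effective
  vaccine look harmful, and a pyramid exchangeability stress test.

## Worked example

The conditional measure VE_H|S need not wane even when both of its inputs
wane — it is a ratio of two effectiveness values that can decay at
different rates:

```r
library(vesimlab)
reproduce_table2()[, c("example", "stratum_label", "ve_s_pct",
                       "ve_h_given_s_pct", "ve_sh_pct")]
#> # A tibble: 4 × 5
#>   example   stratum_label ve_s_pct ve_h_given_s_pct ve_sh_pct
#>   <chr>     <chr>         <chr>    <chr>            <chr>
#> 1 Example 1 Recent        90%      70%              97%
#> 2 Example 1 Longer ago    65%      43%              80%
#> 3 Example 2 Recent        62%      63%              86%
#> 4 Example 2 Longer ago    0%       71%              71%
```

In Example 1 both protections wane at similar rates and the conditional
measure falls (70% → 43%); in Example 2 protection against infection wanes
much faster than protection against hospitalization and the conditional
measure *rises* (63% → 71%).

Confounded uptake, and what stratification buys back:

```r
cfg <- scenario_confounded(seed = 42L)   # uptake rises with age & immunosuppression
coh <- design_cohort(cfg, 2e5)           # observational sample (masked rows only)
te  <- true_estimands(cfg, 4e5, seed = 43L)
truth <- te$value[te$estimand == "VE_SH"]

ve_risk_ratio(coh, "H", truth = truth)
#> <ve_estimate> VE_H = 0.6670  [0.5791, 0.7366]  (n = 200000)
#>   truth = 0.8050, bias = -0.1379

ve_risk_ratio(coh, "H", strata = c("age_group", "immunocompromised"), truth = truth)
#> <ve_estimate> VE_H = 0.7600  [0.6822, 0.8187]  (n = 198390, standardized over age_group x immunocompromised)
#>   truth = 0.8050, bias = -0.0450
#>   note: 1 strata excluded (empty arm or zero unvaccinated risk)
```

The crude estimate understates the true effectiveness because the
vaccinated are older and sicker; standardizing over the confounders moves
the estimate back inside its interval of the truth, and the one sparse
stratum dropped from standardization is counted, never silent.

The collider demonstration (`collider_bias_experiment()`) runs a grid of
latent-risk-factor strengths: with a strong unmeasured factor that raises
symptom and hospitalization risk and blunts the vaccine's symptom
protection, the crude conditional VE against hospitalization among the
symptomatic turns *negative* (apparent harm) while the benchmark conversion
stays protective; measuring the factor and stratifying restores agreement.

A thin command-line wrapper ships in `inst/cli/param-lab.R`
(`outcomes`, `algebra`, `simulate`, `design`, `estimate`, `table2`,
`fixtures` subcommands).

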