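---
title: "Estimating progression parameters for individual-based transmission models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating progression parameters for individual-based transmission models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vesimlab)
```

## The problem

Individual-based transmission models track, for every simulated person, a
vector of baseline characteristics $L$ (age, sex, comorbidities, prior
infection, immunocompromised status, calendar time), an intervention $A$
(vaccination, 0/1), an exposure $E = e$ to a pathogen variant, and the
person's post-exposure fate. Parameterizing such a model requires the
counterfactual probabilities $\Pr(\text{event}^{e,a} = 1 \mid L = l)$ for a
chain of post-exposure events — here infection ($I$), symptoms ($S$),
diagnosis ($D$), hospitalization ($H$), ICU admission ($C$) and death ($M$).
No single epidemiologic study observes all of these quantities, and common
study designs estimate related but different quantities, some of which lack
a causal interpretation altogether. `vesimlab` is a simulation laboratory
for making those differences concrete: it generates populations from a
fully known structural causal model, observes them the way each study
design would, and compares what each design estimates with the causal
ground truth.

## Outcome space

With six binary events there are $2^6 = 64$ conceivable outcome vectors;
precedence constraints shrink that set. Precedence is a relation over
ordered pairs rather than a strict chain, because some events may skip
predecessors (a patient can die without passing through the ICU) while
others cannot (nothing happens without infection). For $n$ events the
feasible count therefore lies between $n + 1$ (strict chain: the
prefix-of-ones patterns) and $2^n$ (no constraints). `enumerate_feasible()`
constructs the feasible set by depth-first assignment in chain order; the
test suite checks it against brute-force filtering of all $2^n$ vectors for
$n \le 8$.

```{r}
nrow(enumerate_feasible(event_chain()))
```

Two chains ship with the package. The generic default (`event_chain()`)
uses: $S$ and $D$ require $I$; $H$ requires $D$; $C$ requires $H$; $M$
requires $H$. Scenario simulations use `default_scenario_chain()`, which
adds the pair $(S, H)$ — hospitalization *for the disease* implies
symptomatic disease. That extra pair matters: the conversion between
marginal and conditional effectiveness below is an identity only when every
hospitalized case is symptomatic, and we wanted the simulated designs to
satisfy the conversion's premise rather than violate it silently.

## Joint versus conditional parameterization

A model that draws a complete post-exposure fate in one step needs the
joint distribution over feasible vectors per stratum; a model that draws
progression step by step needs conditional probabilities given the full
history. `joint_to_conditional()` and `conditional_to_joint()` convert
between the two exactly (round trips hold to $10^{-12}$, enforced in the
tests). Histories that are never reached (zero marginal mass) are
represented by an explicit undefined sentinel (`defined = FALSE`,
`prob = NA`), never by 0: a sequential-draw consumer must distinguish
"never reached" from "never progresses".

## The effectiveness algebra

With $VE_S$ the vaccine effectiveness against symptomatic infection and
$VE_{SH}$ the effectiveness against hospitalization (both one minus a risk
ratio among the exposed), the effectiveness against hospitalization *among
the symptomatically infected* is

$$VE_{H|S} = 1 - \frac{1 - VE_{SH}}{1 - VE_S}.$$

`ve_conditional()` evaluates this; `ve_compose()` inverts it. Both accept
negative values (harm); only $VE_S = 1$ is excluded (no vaccinated cases —
the conditional quotient has no denominator). Because $VE_{H|S}$ is a ratio
of two quantities that can wane at different rates, it is *not* an
effectiveness that must wane: the bundled worked example
(`reproduce_table2()`) shows one pair of profiles in which it falls from
70% to 43% with time since vaccination, and another in which it *rises*
from 63% to 71% because protection against infection wanes much faster than
protection against hospitalization. VE values are stored as proportions
throughout; rendering at nearest-integer percent (`format_percent()`,
round-half-up) is purely a reporting-layer concern.

The severity-pyramid composition `scfr_compose()` multiplies per-level
conditional risks, e.g. $sCFR = r_{D|H} \cdot r_{H|S}$. The product equals
$\Pr(\text{death} \mid \text{symptomatic})$ only when every death passes
through hospitalization, so the function takes the event chain and refuses
chains that permit death without hospitalization.

## The structural causal model

`sample_population()` draws individuals from a `scenario_config()`:

* **Covariate laws.** Age group (default 18–49 / 50–64 / 65+ with
  probabilities 0.55 / 0.25 / 0.20), sex, comorbidity count
  (Poisson, mean 0.8), prior infection (Bernoulli 0.30), immunocompromised
  status (Bernoulli 0.04), an optional latent binary risk factor, and a
  discrete calendar period. These defaults are plausible round numbers for
  an adult population in a respiratory-virus wave; nothing downstream
  depends on their exact values, and every law is configurable.
* **Vaccination.** Either randomized with probability `p`, or assigned by a
  logistic model in the covariates (the confounded preset pushes uptake
  strongly toward the old and the immunocompromised).
* **Exposure.** One binary contact event with probability 0.25 per person,
  with the variant drawn from a per-calendar-period mixture (the default
  moves from delta-dominant to omicron-dominant across two periods).
  An optional multiplier `rr_vaccinated` on the exposure probability of the
  vaccinated encodes a behavioural pathway; 1 means blinded. Full
  transmission dynamics are deliberately out of scope — the estimation
  questions studied here concern post-exposure fates, not epidemic curves.
* **Risk model.** The conditional probability of each event given its
  prerequisites is a baseline (defaults: $I$ 0.5, $S$ 0.6, $D$ 0.7, $H$
  0.08, $C$ 0.25, $M$ 0.12) times multiplicative factors for age,
  immunocompromised status, prior infection, comorbidity count, variant and
  vaccination. Multiplicative products are clipped to $[0,1]$; the number
  of clipped products is counted, attached to the population, and raised as
  a warning, so saturation is never silent. The shipped no-bias, null and
  confounded presets never clip.
* **Frailty.** One log-normal multiplicative susceptibility factor per
  individual, shared across all events (mean 1; `frailty_sd` is the SD of
  its logarithm; 0 disables it). This induces positive correlation among
  an individual's outcomes. Because a log-normal is unbounded, any positive
  frailty SD gives a strictly positive clipping probability; the
  frailty-plus-misclassification preset uses `frailty_sd = 0.25` with
  lowered baselines so clipping is rare (on the order of a few draws per
  thousand individuals), and the clip counter reports whatever occurs.
* **Potential outcomes via common random numbers.** Each individual gets
  one uniform draw per event (plus one for exposure), reused under both
  vaccination arms. Individual-level potential outcomes are therefore well
  defined, arm contrasts carry no independent noise, and under the null the
  two arms are bit-identical. `true_estimands()` computes causal risks,
  $VE_S$, $VE_{SH}$ and the implied $VE_{H|S}$ directly from the potential
  outcomes.
* **Measurement.** Variant calls follow a binary proxy (in the style of
  S-gene target failure) with configurable sensitivity/specificity, as does
  immunocompromised status. True values are kept alongside measured ones in
  the oracle population; study designs expose only the measured copies.
* **Seeds.** One root seed; every stochastic operation derives a child
  stream from it by a fixed label (`derive_seed()`), so adding an operation
  never perturbs the draws of existing ones, and identical
  (config, n, seed) gives bit-identical populations.

## Study designs and masking

Each `design_*()` function selects and masks a simulated population the way
the named design would observe it: challenge trials expose everyone to a
chosen variant and randomize vaccination; RCTs randomize vaccination but do
not record exposure (and refuse scenarios with a behavioural
vaccination-exposure effect, which would violate blinding); cohorts use the
configured, possibly confounded, uptake mechanism; contact-tracing samples
are restricted to the exposed, with selection weights over measured
covariates making non-exchangeable selection first-class; progression
studies ascertain at a chosen event and observe only that event and its
downstream. No study sample ever contains potential-outcome columns or the
latent frailty — `assert_masked()` turns accidental oracle leakage into an
error, so every estimator is a function of data a real study could hold.

## Estimators

`ve_risk_ratio()` is one minus a risk ratio, crude or standardized to the
sample's stratum distribution; `ve_progression()` applies it among those
with the ascertainment event; `progression_risk()` estimates per-level
conditional risks with Wilson intervals. Confidence intervals elsewhere use
the large-sample variance of the log risk ratio, with the standardized
variance from the delta method over stratum-specific binomial risks; exact
small-sample inference is out of scope because no conclusion here depends
on it. Strata with an empty arm or zero unvaccinated risk cannot contribute
a finite ratio and are excluded from standardization with an audited count
(`excluded_strata`) rather than generating infinite ratios — at moderate
sample sizes with rare outcomes this exclusion can visibly shift the
standardized estimate, which is why the parameter-recovery checks run the
stratified estimator under randomized uptake, where strata keep both arms
populated.

## Where the collider bias actually comes from

Conditioning on a post-exposure event such as symptomatic infection opens a
non-causal path between vaccination and hospitalization whenever something
unmeasured influences both symptoms and hospitalization: symptom status is
a common effect (a collider) of vaccination and the latent factor.

A point that shaped the experiment design: under an *exactly*
multiplicative risk model with homogeneous vaccine effects, the distortion
vanishes. If $\Pr(S = 1 \mid u, a) = m_a\, g(u)$ separates in $a$ and $u$,
then the distribution of $u$ among symptomatic cases is the same in both
arms, and the crude conditional risk ratio equals the within-stratum one.
Equally, the conversion $1 - (1 - VE_{SH})/(1 - VE_S)$ applied to the true
marginal effectiveness values is *algebraically identical* to the
population crude conditional risk ratio whenever hospitalization implies
symptoms. The interesting — and realistic — distortions therefore need
either effect heterogeneity or saturation:

* the shipped collider scenarios make the vaccine's symptom protection
  weaker in carriers of the latent risk factor (`vacc_interaction`), as is
  the case for immunosuppressed hosts: vaccinated symptomatic cases are
  then *enriched* in the risk factor relative to unvaccinated symptomatic
  cases, and the crude conditional VE against hospitalization is dragged
  down — in the strong configuration below zero, an apparent harm, while
  the benchmark stays protective;
* unbounded frailty saturates the unvaccinated symptom risk at 1 for the
  most frail, which breaks multiplicative separability the same way;
  the grid's frailty-only row quantifies this, and stratification cannot
  repair it (the frailty is continuous and latent).

The benchmark in `collider_bias_experiment()` is the conversion evaluated
in the matched scenario with the latent effects switched off, at the same
seed — the value the conditional measure would take with no unmeasured
common cause, which is also what a stratified analysis with the risk factor
measured recovers. `collider_measurement_sweep()` shows the residual gap
shrinking as the measurement accuracy of the stratifying variable rises.

## Packaged experiments and problem sizes

All stochastic conclusions use the package-wide convention of three
Monte-Carlo standard errors estimated from replications (default 20).
The sizes used by the shipped checks, chosen to put each contrast well
beyond its Monte-Carlo noise: the trial identity check (marginal versus
exposure-conditional risk ratio) runs 20 replications at $n = 200{,}000$;
the collider grid runs 20 replications at $n = 100{,}000$ per
configuration; the pyramid exchangeability experiment runs 8 replications
at $n = 150{,}000$ per component study; design null/recovery checks use a
single run at $n = 200{,}000$ judged against the estimator's large-sample
standard error, with ground truth evaluated on a larger population
($n = 800{,}000$) so its own Monte-Carlo error is negligible.

## What the generator does and does not emulate

The simulator produces exactly the structures the estimation questions
need: confounded uptake, behavioural exposure effects, variant mixtures
drifting over calendar time, misclassification, shared frailty, and
selection into samples. It does **not** emulate transmission chains,
time-to-event outcomes, waning within a stratum, loss to follow-up, or
test-negative sampling. Passing tests therefore demonstrate properties of
the estimators and designs under a known data-generating process — they do
not validate any particular real-world effectiveness magnitude, and no real
data are fitted anywhere in the package.

## Numerical choices

* Probability tables validate to $10^{-12}$ (mass sums, round trips).
* Percent rendering rounds half up, away from banker's rounding, to match
  epidemiologic reporting.
* Risk products clip at 1 with an audited counter; undefined conditionals
  use an explicit sentinel; excluded strata are counted on the estimate.
* Lexicographic enumeration order (first event most significant) makes
  outcome-space output deterministic.
* All randomness flows from one root seed through labelled child streams.

## Known limitations

Stratification is the only adjustment method provided (no regression
adjustment, no principal-stratification bounds); the conditional
effectiveness measure retains an ambiguous causal interpretation even when
fully adjusted, because the vaccinated-and-infected and
unvaccinated-and-infected populations are different people — the collider
grid quantifies that gap under frailty heterogeneity but does not identify
subgroup effects. Odds-ratio (test-negative) estimators and effects of
vaccination on infectiousness are out of scope.
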