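chain:
  events:
  - I
  - S
  - D
  - H
  - C
  - M
  requires:
  - - I
    - S
  - - I
    - D
  - - S
    - H
  - - D
    - H
  - - H
    - C
  - - H
    - M
covariates:
  age_group:
    type: categorical
    levels:
    - 18-49
    - 50-64
    - 65+
    probs:
    - 0.55
    - 0.25
    - 0.2
  sex:
    type: categorical
    levels:
    - F
    - M
    probs:
    - 0.5
    - 0.5
  comorbidity_count:
    type: poisson
    lambda: 0.8
  prior_infection:
    type: bernoulli
    p: 0.3
  immunocompromised:
    type: bernoulli
    p: 0.04
  risk_factor:
    type: bernoulli
    p: 0.0
  calendar_time:
    type: categorical
    levels:
    - '1'
    - '2'
    probs:
    - 0.5
    - 0.5
vaccination:
  mechanism: randomized
  p: 0.5
exposure:
  p: 0.25
  rr_vaccinated: 1.0
  variants:
  - delta
  - omicron
  mixture:
    '1':
      delta: 0.9
      omicron: 0.1
    '2':
      delta: 0.2
      omicron: 0.8
risk:
  baseline:
    I: 0.45
    S: 0.5
    D: 0.55
    H: 0.06
    C: 0.2
    M: 0.08
  rr_vaccination:
    I: 0.7
    S: 0.6
    D: 1.0
    H: 0.5
    C: 1.0
    M: 0.8
  modifiers:
    age:
      field: age_group
      rr:
        18-49:
          I: 1.0
          S: 1.0
          D: 1.0
          H: 1.0
          C: 1.0
          M: 1.0
        50-64:
          I: 1.0
          S: 1.0
          D: 1.0
          H: 1.4
          C: 1.2
          M: 1.4
        65+:
          I: 1.0
          S: 1.0
          D: 1.0
          H: 1.8
          C: 1.4
          M: 1.8
    immunocompromised:
      field: immunocompromised
      rr:
        I: 1.0
        S: 1.0
        D: 1.0
        H: 1.5
        C: 1.0
        M: 1.5
    prior_infection:
      field: prior_infection
      rr:
        I: 0.6
        S: 0.8
        D: 1.0
        H: 1.0
        C: 1.0
        M: 1.0
    comorbidity:
      field: comorbidity_count
      rr:
        I: 1.0
        S: 1.0
        D: 1.0
        H: 1.1
        C: 1.0
        M: 1.1
    variant:
      field: variant
      rr:
        delta:
          I: 1.0
          S: 1.0
          D: 1.0
          H: 1.0
          C: 1.0
          M: 1.0
        omicron:
          I: 1.0
          S: 0.9
          D: 1.0
          H: 0.5
          C: 1.0
          M: 0.6
  vacc_interaction: ~
frailty_sd: 0.25
misclassification:
  variant:
    sensitivity: 0.9
    specificity: 0.95
  immunocompromised:
    sensitivity: 0.9
    specificity: 0.95
observation:
  risk_factor_measured: yes
seed: 1
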