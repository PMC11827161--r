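window:
- -10.0
- 15.0
fp:
  powers:
  - 0.0
  - 1.0
  shift: -11.0
  scale: 10.4
marginals:
  age_mean: 27.1
  age_sd: 6.6
  age_bounds:
  - 14.0
  - 45.0
  townsend:
  - 0.212
  - 0.2035
  - 0.209
  - 0.2158
  - 0.1597
  townsend_missing: 0.0011
  ethnicity:
    white: 0.865
    nonwhite: 0.102
    unknown: 0.033
  smoking: 0.45
  parity:
  - 0.4164
  - 0.2813
  - 0.1502
  - 0.0801
  - 0.072
  nonsingleton: 0.011
  med_antihypertensive: 0.059
  med_lipid_lowering: 0.003
  med_hypoglycaemic: 0.01
  hes_linked: 0.5451
apo:
  targets:
    gestational_hypertension: 0.094
    preeclampsia: 0.04
    gestational_diabetes: 0.04
    ptb_spontaneous: 0.056
    ptb_indicated: 0.031
    sga: 0.124
    lga: 0.117
    stillbirth: 0.007
    congenital_anomaly: 0.031
    miscarriage_any: 0.186
    miscarriage_multiple: 0.006
  frailty:
    values:
    - -10.0
    - 0.0
    - 1.0
    probs:
    - 0.15
    - 0.68
    - 0.17
  gamma: 0.55
  rho: -6.0
  rho_recur: 0.42
  sat: -0.25
  delta: 0.5
  count_targets:
    '0': 0.717
    '1': 0.212
    '2': 0.057
    3+: 0.015
timing:
  gap:
  - 1.0
  - 4.0
  gestation_live: 0.75
  gestation_miscarriage: 0.55
truth:
  sbp:
    anchors:
      groups:
      - '0'
      - '1'
      - '2'
      - 3+
      times:
      - -10.0
      - 0.0
      - 10.0
      values:
      - - 112.9
        - 116.3
        - 119.5
      - - 115.1
        - 118.2
        - 121.2
      - - 116.8
        - 120.5
        - 124.3
      - - 119.6
        - 123.2
        - 127.1
    sd_u: 9.0
    sd_e: 8.0
    bounds:
    - 60.0
    - 250.0
    effects:
      age: 0.1
      townsend: 0.4
      smoking: 1.5
      parity: -0.3
      nonsingleton: 0.0
      nonwhite: -1.0
      med_antihypertensive: 6.0
      med_lipid_lowering: 1.0
      med_hypoglycaemic: 1.0
  dbp:
    anchors:
      groups:
      - '0'
      - '1'
      - '2'
      - 3+
      times:
      - -10.0
      - 0.0
      - 10.0
      values:
      - - 70.0
        - 72.0
        - 74.0
      - - 71.2
        - 73.2
        - 75.2
      - - 72.5
        - 74.5
        - 76.5
      - - 74.0
        - 76.0
        - 78.0
    sd_u: 7.0
    sd_e: 6.5
    bounds:
    - 40.0
    - 150.0
    effects:
      age: 0.06
      townsend: 0.25
      smoking: 1.0
      parity: -0.2
      nonsingleton: 0.0
      nonwhite: -0.5
      med_antihypertensive: 4.0
      med_lipid_lowering: 0.5
      med_hypoglycaemic: 0.5
  bmi:
    anchors:
      groups:
      - '0'
      - '1'
      - '2'
      - 3+
      times:
      - -10.0
      - 0.0
      - 10.0
      values:
      - - 23.0
        - 24.2
        - 25.5
      - - 23.8
        - 25.0
        - 26.3
      - - 24.8
        - 26.0
        - 27.3
      - - 26.0
        - 27.2
        - 28.5
    sd_u: 3.5
    sd_e: 1.2
    bounds:
    - 13.0
    - 70.0
    effects:
      age: 0.03
      townsend: 0.25
      smoking: -0.3
      parity: 0.2
      nonsingleton: 0.0
      nonwhite: 0.3
      med_antihypertensive: 1.5
      med_lipid_lowering: 0.8
      med_hypoglycaemic: 1.5
  total_chol:
    anchors:
      groups:
      - '0'
      - '1'
      - '2'
      - 3+
      times:
      - -10.0
      - 0.0
      - 10.0
      values:
      - - 4.55
        - 4.7
        - 4.9
      - - 4.65
        - 4.8
        - 5.0
      - - 4.8
        - 4.95
        - 5.15
      - - 4.95
        - 5.1
        - 5.3
    sd_u: 0.7
    sd_e: 0.45
    bounds:
    - 1.5
    - 15.0
    effects:
      age: 0.01
      townsend: 0.02
      smoking: 0.1
      parity: 0.0
      nonsingleton: 0.0
      nonwhite: 0.0
      med_antihypertensive: 0.1
      med_lipid_lowering: 0.6
      med_hypoglycaemic: 0.2
  hdl_chol:
    anchors:
      groups:
      - '0'
      - '1'
      - '2'
      - 3+
      times:
      - -10.0
      - 0.0
      - 10.0
      values:
      - - 1.55
        - 1.52
        - 1.47
      - - 1.52
        - 1.49
        - 1.44
      - - 1.49
        - 1.46
        - 1.41
      - - 1.45
        - 1.42
        - 1.37
    sd_u: 0.28
    sd_e: 0.18
    bounds:
    - 0.3
    - 5.0
    effects:
      age: 0.0
      townsend: -0.01
      smoking: -0.06
      parity: 0.0
      nonsingleton: 0.0
      nonwhite: 0.0
      med_antihypertensive: 0.0
      med_lipid_lowering: -0.05
      med_hypoglycaemic: -0.05
  glucose:
    anchors:
      groups:
      - '0'
      - '1'
      - '2'
      - 3+
      times:
      - -10.0
      - 0.0
      - 10.0
      values:
      - - 4.8
        - 4.9
        - 5.05
      - - 4.9
        - 5.0
        - 5.15
      - - 5.05
        - 5.15
        - 5.3
      - - 5.3
        - 5.4
        - 5.55
    sd_u: 0.5
    sd_e: 0.6
    bounds:
    - 2.0
    - 30.0
    effects:
      age: 0.005
      townsend: 0.01
      smoking: 0.05
      parity: 0.0
      nonsingleton: 0.0
      nonwhite: 0.1
      med_antihypertensive: 0.05
      med_lipid_lowering: 0.05
      med_hypoglycaemic: 0.8
      fasting: -0.6
obs:
  sbp:
    mu: 7.0
    size: 1.3
    mult:
    - 1.0
    - 1.25
    - 1.4
    - 1.55
  dbp:
    mu: 7.0
    size: 1.3
    mult:
    - 1.0
    - 1.25
    - 1.4
    - 1.55
  bmi:
    mu: 3.6
    size: 1.2
    mult:
    - 1.0
    - 1.3
    - 1.45
    - 1.6
  total_chol:
    mu: 0.263
    size: 1.0
    mult:
    - 1.0
    - 1.45
    - 1.7
    - 1.95
  hdl_chol:
    mu: 0.263
    size: 1.0
    mult:
    - 1.0
    - 1.45
    - 1.7
    - 1.95
  glucose:
    mu: 0.8
    size: 1.0
    mult:
    - 1.0
    - 1.3
    - 1.5
    - 1.7
    fasting_prob: 0.35
outcomes:
- sbp
- dbp
- bmi
- total_chol
- hdl_chol
- glucose
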