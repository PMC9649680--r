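# HFpEF cohort parameterisation (EMPEROR-Preserved-derived inputs, 2022 USD).
# CV-death incidences are 8.2% (control) / 7.3% (empagliflozin): these are the
# source trial's published figures and the only pair that reproduces the
# per-cycle probabilities 0.00975 / 0.00864 under the 26.2-month follow-up.
cycle:
  length_months: 3
  horizon_years: 10
  annual_discount_rate: 0.05
  discount_range: [0.0, 0.08]

population:
  label: HFpEF
  start_age: 65
  initial_nyha_mix: {I: 0.00, II: 0.75, III: 0.24, IV: 0.01}

events:
  control:
    cv_death:            # 8.2% over 26.2 months -> 0.00975 per cycle
      incidence: 0.082
      followup_months: 26.2
      range: [0.00877, 0.01072]
      dist: beta
    hospitalisation:     # 16.2% over 26.2 months -> 0.02003 per cycle
      incidence: 0.162
      followup_months: 26.2
      range: [0.01803, 0.02204]
      dist: beta
  empagliflozin:
    cv_death:            # 7.3% over 26.2 months -> 0.00864 per cycle
      incidence: 0.073
      followup_months: 26.2
      range: [0.00778, 0.00951]
      dist: beta
    hospitalisation:     # 12.1% over 26.2 months -> 0.01466 per cycle
      incidence: 0.121
      followup_months: 26.2
      range: [0.01319, 0.01613]
      dist: beta
  readmission:           # 30-day post-discharge risk 18% as monthly rate -> 0.417
    rate_per_month: 0.18
    range: [0.3753, 0.4587]
    dist: beta

transition_matrix:
  - [0.977, 0.019, 0.004, 0.000]
  - [0.008, 0.981, 0.010, 0.001]
  - [0.000, 0.034, 0.960, 0.006]
  - [0.000, 0.000, 0.055, 0.945]

mortality_non_cv:
  extrapolation: carry_forward
  bands:
    - {age_from: 65, age_to: 69, p_cycle: 0.002430}
    - {age_from: 70, age_to: 74, p_cycle: 0.003042}
    - {age_from: 75, age_to: 79, p_cycle: 0.004185}

utilities:
  by_nyha:
    I:   {value: 1.000, range: [0.950, 1.000], dist: beta}
    II:  {value: 0.830, range: [0.789, 0.872], dist: beta}
    III: {value: 0.550, range: [0.523, 0.578], dist: beta}
    IV:  {value: 0.270, range: [0.257, 0.284], dist: beta}
  hosp_disutility: {value: -0.1, range: [-0.13, -0.08], dist: beta}
  hosp_disutility_mode: absolute_qaly

costs:
  standard_therapy_per_cycle: {value: 131.96, range: [131.96, 310.83], dist: gamma}
  drug_per_cycle:             {value: 59.63,  range: [47.70, 71.55],   dist: gamma}
  hosp_cost_per_event:        {value: 1783.39, range: [1029.73, 3336.39], dist: gamma}

wtp: [12652.5, 37957.5]

psa:
  dirichlet_ess: 1000

scenarios:
  - {name: national_purchase_price, drug_per_cycle: 24.75}
  - {name: town_hospital,        hosp_cost_per_event: 1029.73}
  - {name: county_hospital,      hosp_cost_per_event: 1231.06}
  - {name: municipal_hospital,   hosp_cost_per_event: 1783.39}
  - {name: provincial_hospital,  hosp_cost_per_event: 1949.55}
  - {name: ministerial_hospital, hosp_cost_per_event: 3336.39}
  - {name: horizon_15y, horizon_years: 15}
  - {name: horizon_20y, horizon_years: 20}
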