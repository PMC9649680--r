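# HFrEF cohort parameterisation (EMPEROR-Reduced-derived inputs, 2022 USD).
# Event entries give trial-level cumulative incidences with their follow-up;
# ranges are on the per-cycle probability scale and drive OWSA/PSA.
cycle:
  length_months: 3
  horizon_years: 10
  annual_discount_rate: 0.05
  discount_range: [0.0, 0.08]

population:
  label: HFrEF
  start_age: 65
  # baseline NYHA distribution (assumption; resembles the source trial's
  # predominantly class II/III enrolment)
  initial_nyha_mix: {I: 0.00, II: 0.75, III: 0.24, IV: 0.01}

events:
  control:
    cv_death:            # 10.8% over 16 months -> 0.0212 per cycle
      incidence: 0.108
      followup_months: 16
      range: [0.01908, 0.02332]
      dist: beta
    hospitalisation:     # 18.3% over 16 months -> 0.03719 per cycle
      incidence: 0.183
      followup_months: 16
      range: [0.03347, 0.04091]
      dist: beta
  empagliflozin:
    cv_death:            # 10.0% over 16 months -> 0.01956 per cycle
      incidence: 0.100
      followup_months: 16
      range: [0.01760, 0.02152]
      dist: beta
    hospitalisation:     # 13.2% over 16 months -> 0.02619 per cycle
      incidence: 0.132
      followup_months: 16
      range: [0.02357, 0.02881]
      dist: beta
  readmission:           # 30-day post-discharge risk 13.4% as monthly rate -> 0.331
    rate_per_month: 0.134
    range: [0.2979, 0.3641]
    dist: beta

# 3-month NYHA transition probabilities (rows: from I..IV), Dirichlet in PSA
transition_matrix:
  - [0.977, 0.019, 0.004, 0.000]
  - [0.008, 0.981, 0.010, 0.001]
  - [0.000, 0.034, 0.960, 0.006]
  - [0.000, 0.000, 0.055, 0.945]

mortality_non_cv:        # per-cycle (3-month) probabilities by age band
  extrapolation: carry_forward
  bands:
    - {age_from: 65, age_to: 69, p_cycle: 0.002430}
    - {age_from: 70, age_to: 74, p_cycle: 0.003042}
    - {age_from: 75, age_to: 79, p_cycle: 0.004185}

utilities:
  by_nyha:
    I:   {value: 1.000, range: [0.950, 1.000], dist: beta}
    II:  {value: 0.860, range: [0.817, 0.903], dist: beta}
    III: {value: 0.600, range: [0.570, 0.630], dist: beta}
    IV:  {value: 0.280, range: [0.266, 0.294], dist: beta}
  hosp_disutility: {value: -0.1, range: [-0.13, -0.08], dist: beta}
  hosp_disutility_mode: absolute_qaly

costs:                   # USD per 3-month cycle / per hospitalisation event
  standard_therapy_per_cycle: {value: 131.96, range: [131.96, 310.83], dist: gamma}
  drug_per_cycle:             {value: 59.63,  range: [47.70, 71.55],   dist: gamma}
  hosp_cost_per_event:        {value: 1783.39, range: [1029.73, 3336.39], dist: gamma}

wtp: [12652.5, 37957.5]  # 1x and 3x 2021 GDP per capita, USD/QALY

psa:
  dirichlet_ess: 1000

scenarios:
  - {name: national_purchase_price, drug_per_cycle: 24.75}  # $0.275/10 mg x 90 d
  - {name: town_hospital,        hosp_cost_per_event: 1029.73}
  - {name: county_hospital,      hosp_cost_per_event: 1231.06}
  - {name: municipal_hospital,   hosp_cost_per_event: 1783.39}
  - {name: provincial_hospital,  hosp_cost_per_event: 1949.55}
  - {name: ministerial_hospital, hosp_cost_per_event: 3336.39}
  - {name: horizon_15y, horizon_years: 15}
  - {name: horizon_20y, horizon_years: 20}
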