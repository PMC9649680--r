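# Shared fixtures: bundled configs loaded once; small toy parameter sets
# built in code.

hfref <- load_parameter_set(hf_config_path("hfref"))
hfpef <- load_parameter_set(hf_config_path("hfpef"))

# a cohort that can only die of CV causes, with flat utility and simple costs
toy_death_only <- function(p_death = 0.5, utility = 0.8, cost = 100,
                           horizon_years = 0.5, discount = 0) {
  make_parameter_set(
    cycle = cycle_spec(3, horizon_years, discount),
    p_cv_death = c(control = p_death, empagliflozin = p_death),
    p_hosp = c(control = 0, empagliflozin = 0),
    p_readmit = 0,
    utilities = rep(utility, 4),
    hosp_disutility = 0,
    cost_standard = cost, cost_drug = 0, cost_hosp = 0,
    initial_nyha_mix = c(0, 1, 0, 0))
}

# immortal, event-free cohort at full health
toy_immortal <- function(horizon_years = 10, discount = 0) {
  make_parameter_set(
    cycle = cycle_spec(3, horizon_years, discount),
    p_cv_death = c(control = 0, empagliflozin = 0),
    p_hosp = c(control = 0, empagliflozin = 0),
    p_readmit = 0,
    utilities = rep(1, 4),
    hosp_disutility = 0,
    cost_standard = 0, cost_drug = 0, cost_hosp = 0,
    initial_nyha_mix = c(0, 1, 0, 0))
}

expect_state_vector <- function(occ, tol = 1e-9) {
  expect_true(all(abs(rowSums(occ) - 1) < tol))
  expect_true(all(occ >= -1e-12))
}
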