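test_that("discount factors follow (1+r)^(-t) on the cycle grid", {
  spec <- cycle_spec(3, 10, 0.05)
  expect_equal(discount_factor(0, spec), 1)
  expect_equal(discount_factor(4, spec), 1 / 1.05)
  expect_equal(discount_factor(40, spec), 1.05^-10)
})

test_that("non-CV mortality lookup selects bands and extrapolates", {
  mort <- hfref$mortality_non_cv
  expect_equal(non_cv_death_prob(65, mort), 0.002430)
  expect_equal(non_cv_death_prob(69.75, mort), 0.002430)
  expect_equal(non_cv_death_prob(70, mort), 0.003042)
  expect_equal(non_cv_death_prob(79, mort), 0.004185)
  # beyond the last band: carry-forward default
  expect_equal(non_cv_death_prob(85, mort), 0.004185)
  # log-linear extrapolation continues the increasing trend
  mort_ll <- mort
  mort_ll$extrapolation <- "log_linear"
  expect_gt(non_cv_death_prob(85, mort_ll), 0.004185)
  expect_lte(non_cv_death_prob(120, mort_ll), 1)
})

test_that("absorbing states are absorbing and identity dynamics hold still", {
  dead <- c(rep(0, 8), 1, 0)
  out <- step_cycle(dead, hfref, "control", 65)
  expect_equal(out$membership, dead)
  expect_equal(out$expected_events, 0)

  quiet <- toy_immortal()
  m0 <- c(0, 1, rep(0, 8))
  out <- step_cycle(m0, quiet, "control", 65)
  expect_equal(out$membership, m0)
  expect_equal(out$expected_events, 0)

  expect_error(step_cycle(rep(0.2, 10), hfref, "control", 65), "summing to 1")
})

test_that("a single cycle from 100% NYHA II reproduces the hand computation", {
  p_cv <- cumulative_incidence_to_cycle_prob(0.108, 16)
  p_hosp <- cumulative_incidence_to_cycle_prob(0.183, 16)
  p_ncv <- 0.002430
  p_death <- 1 - (1 - p_cv) * (1 - p_ncv)

  m0 <- c(0, 1, rep(0, 8))
  out <- step_cycle(m0, hfref, "control", 65)
  m1 <- out$membership

  expect_equal(m1[9] + m1[10], p_death)
  # deaths apportioned proportionally to the single-cause probabilities
  expect_equal(m1[9] / (m1[9] + m1[10]), p_cv / (p_cv + p_ncv))
  # hospitalisation strikes survivors at the baseline probability
  expect_equal(out$expected_events, (1 - p_death) * p_hosp)
  # survivors spread over NYHA classes by the published row for class II
  M <- hfref$transition_matrix
  expect_equal(m1[1:4] + m1[5:8], (1 - p_death) * unname(M[2, ]))
  # hospitalised fraction of each destination class carries the tunnel flag
  expect_equal(unname(m1[5:8] / (m1[1:4] + m1[5:8])), rep(p_hosp, 4))
  expect_equal(sum(m1), 1)
})

test_that("the cohort trace composes single steps and conserves mass", {
  tr <- run_cohort(hfref, "control")
  expect_equal(nrow(tr), 41)
  occ <- as.matrix(tr[, 3:12])
  expect_state_vector(occ)
  # absorbing occupancies never decrease
  expect_true(all(diff(tr$cv_death) >= 0))
  expect_true(all(diff(tr$non_cv_death) >= 0))
  expect_true(all(tr$events >= 0))
  # first trace row after the start equals one explicit step
  one <- step_cycle(occ[1, ], hfref, "control", 65)
  expect_equal(unname(occ[2, ]), one$membership)
  expect_equal(tr$events[2], one$expected_events)
})

test_that("an event-free immortal cohort stays fully alive for the whole horizon", {
  tr <- run_cohort(toy_immortal(), "control")
  expect_equal(nrow(tr), 41)
  expect_equal(tr$alive, rep(1, 41))
  expect_equal(sum(tr$events), 0)
})

test_that("the higher control-arm CV-death probability yields more cumulative CV deaths", {
  tr_c <- run_cohort(hfref, "control")
  tr_e <- run_cohort(hfref, "empagliflozin")
  expect_gt(tr_c$cv_death[41], tr_e$cv_death[41])
})

test_that("accumulation matches hand-computed trapezoidal totals on a 2-cycle toy", {
  # p(death) = 0.5/cycle, utility 0.8, $100/cycle, no discounting, 2 cycles:
  # alive nodes 1, 0.5, 0.25 -> trapezoid weights 0.75 and 0.375
  toy <- toy_death_only(p_death = 0.5, utility = 0.8, cost = 100,
                        horizon_years = 0.5, discount = 0)
  res <- run_arm(toy, "control")
  expect_equal(res$total_discounted_qalys, 0.25 * 0.8 * (0.75 + 0.375))
  expect_equal(res$total_discounted_cost, 100 * (0.75 + 0.375))
  expect_equal(res$life_years, 0.25 * (0.75 + 0.375))

  # all-dead cohort accrues nothing
  dead_toy <- toy_death_only(p_death = 1, horizon_years = 0.5)
  tr <- run_cohort(dead_toy, "control")
  res2 <- accumulate(tr, dead_toy, "control")
  # only the half-cycle sliver of the first cycle remains
  expect_equal(res2$total_discounted_qalys, 0.25 * 0.8 / 2)
  expect_equal(res2$total_discounted_cost, 100 / 2)
})

test_that("half-cycle correction is the identity under constant full-health membership", {
  res <- run_arm(toy_immortal(horizon_years = 10), "control")
  expect_equal(res$total_discounted_qalys, 10)
  expect_equal(res$life_years, 10)
})

test_that("zero discounting makes discounted and undiscounted totals identical", {
  p0 <- load_parameter_set(hf_config_path("hfref"))
  p0$cycle$annual_discount_rate <- 0
  for (arm in c("control", "empagliflozin")) {
    res <- run_arm(p0, arm)
    expect_identical(res$total_discounted_cost, res$total_undiscounted_cost)
    expect_identical(res$total_discounted_qalys, res$total_undiscounted_qalys)
  }
})

test_that("raising a death probability never raises QALYs; raising drug cost never cuts cost", {
  for (s in 1:5) {
    p <- generate_random_param_set(100 + s)
    base <- run_arm(p, "empagliflozin")
    for (par in c("p_cv_death_empagliflozin")) {
      worse <- set_model_param(p, par, min(1, p$events$empagliflozin$p_cv_death$value + 0.05))
      expect_lte(run_arm(worse, "empagliflozin")$total_discounted_qalys,
                 base$total_discounted_qalys)
    }
    dearer <- set_model_param(p, "cost_drug",
                              p$costs$drug_per_cycle$value + 500)
    expect_gte(run_arm(dearer, "empagliflozin")$total_discounted_cost,
               base$total_discounted_cost)
  }
})

test_that("trace CSV export writes one row per cycle node with payoff columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(run_cohort(hfref, "control"), hfref, "control", path)
  out <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(out), 41)
  expect_true(all(c("I", "IV_post", "events", "discount", "qaly_node",
                    "cost_node", "cost_events") %in% names(out)))
})
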