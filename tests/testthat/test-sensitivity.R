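test_that("beta and gamma fits reproduce the requested moments", {
  # closed-form beta method of moments
  d <- parameterise_distribution(0.3, c(0.2, 0.4), "beta")
  s <- 0.1 / qnorm(0.975)
  a <- 0.3 * (0.3 * 0.7 / s^2 - 1)
  expect_equal(d$shape1, a)
  expect_equal(d$shape2, a * 0.7 / 0.3)
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.3)

  # zero-width range gives a point mass
  d0 <- parameterise_distribution(0.5, c(0.5, 0.5), "beta")
  expect_equal(d0$kind, "point_mass")
  expect_equal(unique(d0$sample(10)), 0.5)

  # infeasible beta moments (mean 1) fall back to a point mass with a warning
  expect_warning(d1 <- parameterise_distribution(1, c(0.95, 1), "beta"),
                 "infeasible")
  expect_equal(unique(d1$sample(5)), 1)

  # gamma fitted to the hospitalisation cost reproduces its mean by Monte Carlo
  dg <- parameterise_distribution(1783.39, c(1029.73, 3336.39), "gamma")
  set.seed(1)
  x <- dg$sample(1e6)
  expect_lt(abs(mean(x) - 1783.39), 3 * sd(x) / sqrt(1e6))
})

test_that("PSA sample means converge to the point estimates", {
  tab <- sa_parameter_table(hfref)
  rownames(tab) <- tab$name
  set.seed(2)
  for (nm in c("p_cv_death_control", "utility_III", "cost_hospitalisation")) {
    r <- tab[nm, ]
    d <- parameterise_distribution(r$value, c(r$low, r$high),
                                   if (r$dist == "gamma") "gamma" else "beta")
    x <- d$sample(1e4)
    expect_lt(abs(mean(x) - r$value), 3 * sd(x) / sqrt(1e4))
  }
})

test_that("Dirichlet-sampled transition rows keep structure and recentre on the base matrix", {
  set.seed(3)
  tm <- sample_transition_matrices(hfref$transition_matrix, 500, ess = 1000)
  expect_true(all(abs(apply(tm, c(1, 2), sum) - 1) < 1e-9))
  # structural zeros preserved in every draw
  expect_true(all(tm[, 1, 4] == 0))
  expect_true(all(tm[, 4, 1] == 0))
  expect_true(all(tm[, 4, 2] == 0))
  expect_true(all(tm[, 3, 1] == 0))
  expect_lt(abs(mean(tm[, 2, 2]) - 0.981), 0.002)
  # non-finite effective sample size pins the matrix
  tm0 <- sample_transition_matrices(hfref$transition_matrix, 3, ess = Inf)
  expect_equal(tm0[2, , ], unname(hfref$transition_matrix))
})

test_that("the tornado ranks the CV-death probabilities first in both populations", {
  for (p in list(hfref, hfpef)) {
    ow <- one_way_sa(p)
    expect_true(all(ow$swing >= 0))
    expect_true(!is.unsorted(rev(ow$swing)))
    expect_setequal(ow$parameter[1:2],
                    c("p_cv_death_control", "p_cv_death_empagliflozin"))
  }
})

test_that("a zero-width range gives zero swing and cheaper drug strictly lowers the ICER", {
  p <- make_parameter_set(p_cv_death = c(control = 0.03, empagliflozin = 0.02),
                          p_hosp = c(control = 0.04, empagliflozin = 0.03),
                          transition_matrix = hfref$transition_matrix)
  ow <- one_way_sa(p)   # all ranges degenerate by construction
  expect_true(all(ow$swing == 0))

  icer_of <- function(pp) {
    inc <- compute_incremental(run_arm(pp, "empagliflozin"),
                               run_arm(pp, "control"))
    inc$delta_cost / inc$delta_qalys
  }
  drug <- hfref$costs$drug_per_cycle$value
  icers <- vapply(c(drug, drug * 0.75, drug * 0.5), function(cd)
    icer_of(set_model_param(hfref, "cost_drug", cd)), numeric(1))
  expect_true(all(diff(icers) < 0))
})

test_that("the PSA is seed-reproducible and degenerate distributions collapse to the base case", {
  a <- run_psa(hfref, n = 20, seed = 99)
  b <- run_psa(hfref, n = 20, seed = 99)
  expect_identical(a$delta_cost, b$delta_cost)
  expect_identical(a$delta_qalys, b$delta_qalys)
  expect_false(identical(a$delta_cost, run_psa(hfref, n = 20, seed = 100)$delta_cost))

  # point-mass everything: every draw equals the base-case increments
  p <- make_parameter_set(p_cv_death = c(control = 0.03, empagliflozin = 0.02),
                          p_hosp = c(control = 0.04, empagliflozin = 0.03),
                          transition_matrix = hfref$transition_matrix)
  p$psa$dirichlet_ess <- Inf
  base <- compute_incremental(run_arm(p, "empagliflozin"), run_arm(p, "control"))
  deg <- run_psa(p, n = 5, seed = 1)
  expect_equal(deg$delta_cost, rep(base$delta_cost, 5))
  expect_equal(deg$delta_qalys, rep(base$delta_qalys, 5))
})

test_that("PSA draws respect parameter constraints", {
  ps <- run_psa(hfref, n = 200, seed = 17)
  s <- attr(ps, "samples")
  probs <- s[, c("p_cv_death_control", "p_cv_death_empagliflozin",
                 "p_hosp_control", "p_hosp_empagliflozin", "p_readmit")]
  expect_true(all(probs >= 0 & probs <= 1))
  U <- s[, paste0("utility_", c("I", "II", "III", "IV"))]
  expect_true(all(U[, 1] >= U[, 2] & U[, 2] >= U[, 3] & U[, 3] >= U[, 4]))
  expect_true(all(s[, c("cost_standard_therapy", "cost_drug",
                        "cost_hospitalisation")] > 0))
})

test_that("CEAC probabilities follow the net-monetary-benefit sign logic", {
  draws <- data.frame(delta_cost = c(100, -50), delta_qalys = c(0.01, 0.02))
  expect_equal(ceac(draws, 5000)$prob_cost_effective, 0.5)
  # all draws cost more: nothing is cost-effective at WTP 0
  pos <- data.frame(delta_cost = c(10, 20), delta_qalys = c(0.1, 0.2))
  expect_equal(ceac(pos, 0)$prob_cost_effective, 0)
  # a single draw with positive NMB gives probability 1
  one <- data.frame(delta_cost = 10, delta_qalys = 0.1)
  expect_equal(ceac(one, 1000)$prob_cost_effective, 1)
  # ties (NMB exactly 0) count as not cost-effective
  tie <- data.frame(delta_cost = 100, delta_qalys = 0.01)
  expect_equal(ceac(tie, 10000)$prob_cost_effective, 0)
  expect_error(ceac(data.frame(delta_cost = numeric(), delta_qalys = numeric()),
                    1000), "non-empty")
})

test_that("CEAC limit identities hold on PSA draws", {
  ps <- run_psa(hfref, n = 200, seed = 31)
  # at WTP 0, probability equals the fraction of strictly cost-saving draws
  expect_equal(ceac(ps, 0)$prob_cost_effective, mean(ps$delta_cost < 0))
  # monotone non-decreasing in WTP when all draws gain QALYs
  gain <- ps[ps$delta_qalys >= 0, ]
  grid <- seq(0, 1e5, length.out = 25)
  expect_true(!is.unsorted(ceac(gain, grid)$prob_cost_effective))
  # at very large WTP the probability approaches the share of QALY-gaining draws
  expect_equal(ceac(ps, 1e12)$prob_cost_effective,
               mean(ps$delta_qalys > 0 |
                      (ps$delta_qalys == 0 & ps$delta_cost < 0)))
})

test_that("scenario runner applies overrides and preserves the base case", {
  sc <- run_scenarios(hfref)
  expect_equal(sc$scenario[1], "base_case")
  base_icer <- sc$icer[1]
  # a no-override scenario reproduces the base case exactly
  none <- run_scenarios(hfref, list(list(name = "noop")))
  expect_equal(none$icer[2], base_icer)
  # municipal hospital row is the base-case hospitalisation cost
  expect_equal(sc$icer[sc$scenario == "municipal_hospital"], base_icer)
  expect_error(apply_scenario(hfref, list(name = "bad", nonsense = 1)),
               "unknown scenario override")
})
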