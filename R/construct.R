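#' Build a parameter set from plain values
#'
#' Programmatic counterpart of [load_parameter_set()], used for toy models,
#' property tests, and the random-parameter generator. Ranges default to the
#' point value (degenerate), so every sensitivity distribution is a point
#' mass unless ranges are supplied.
#'
#' @param label population label.
#' @param cycle a [cycle_spec()].
#' @param p_cv_death named pair `c(control = , empagliflozin = )` of per-cycle
#'   CV-death probabilities.
#' @param p_hosp named pair of per-cycle hospitalisation probabilities.
#' @param p_readmit per-cycle readmission probability (shared across arms).
#' @param transition_matrix 4x4 NYHA transition matrix.
#' @param mortality_bands data.frame with `age_from`, `age_to`, `p_cycle`.
#' @param utilities length-4 vector of NYHA I-IV utilities (non-increasing).
#' @param hosp_disutility magnitude of the per-admission utility decrement.
#' @param hosp_disutility_mode `"cycle_weight"` or `"absolute_qaly"`.
#' @param cost_standard,cost_drug per-cycle costs (USD).
#' @param cost_hosp cost per hospitalisation event (USD).
#' @param start_age cohort starting age in years.
#' @param initial_nyha_mix length-4 fractions over NYHA I-IV summing to 1.
#' @param wtp pair of willingness-to-pay thresholds.
#' @param extrapolation mortality extrapolation beyond the last band.
#' @return a validated `hf_params`.
#' @export
make_parameter_set <- function(label = "toy",
                               cycle = cycle_spec(),
                               p_cv_death = c(control = 0.02, empagliflozin = 0.02),
                               p_hosp = c(control = 0.03, empagliflozin = 0.03),
                               p_readmit = 0.3,
                               transition_matrix = diag(4),
                               mortality_bands = data.frame(
                                 age_from = 65, age_to = 200, p_cycle = 0),
                               utilities = c(1, 0.85, 0.6, 0.3),
                               hosp_disutility = 0.1,
                               hosp_disutility_mode = "cycle_weight",
                               cost_standard = 100, cost_drug = 50,
                               cost_hosp = 1000,
                               start_age = 65,
                               initial_nyha_mix = c(0, 0.75, 0.24, 0.01),
                               wtp = c(12652.5, 37957.5),
                               extrapolation = "carry_forward") {
  M <- transition_matrix
  dimnames(M) <- list(nyha_levels, nyha_levels)
  mix <- initial_nyha_mix
  names(mix) <- nyha_levels
  by_nyha <- lapply(utilities, new_param)
  names(by_nyha) <- nyha_levels
  params <- structure(
    list(cycle = cycle,
         events = list(
           control = list(p_cv_death = new_param(unname(p_cv_death["control"])),
                          p_hosp = new_param(unname(p_hosp["control"]))),
           empagliflozin = list(
             p_cv_death = new_param(unname(p_cv_death["empagliflozin"])),
             p_hosp = new_param(unname(p_hosp["empagliflozin"]))),
           p_readmit = new_param(p_readmit)),
         transition_matrix = M,
         mortality_non_cv = list(bands = mortality_bands,
                                 extrapolation = extrapolation),
         utilities = list(by_nyha = by_nyha,
                          hosp_disutility = new_param(hosp_disutility),
                          hosp_disutility_mode = hosp_disutility_mode),
         costs = list(standard_therapy_per_cycle = new_param(cost_standard),
                      drug_per_cycle = new_param(cost_drug),
                      hosp_cost_per_event = new_param(cost_hosp)),
         population = list(label = label, start_age = start_age,
                           initial_nyha_mix = mix),
         discount = new_param(cycle$annual_discount_rate),
         wtp = wtp,
         scenarios = NULL,
         psa = list(dirichlet_ess = 1000)),
    class = "hf_params")
  validate_parameter_set(params)
  params
}

#' Generate a random valid parameter set
#'
#' Draws per-cycle probabilities uniformly in `[0, 0.3]`, ordered utilities in
#' `[0, 1]`, costs in `(0, 10^4)`, non-decreasing non-CV mortality bands, a
#' Dirichlet-perturbed NYHA transition matrix preserving the structural zeros
#' of the published matrix, a random initial NYHA mix, and a discount rate in
#' `[0, 0.08]`. Always passes [validate_parameter_set()] by construction.
#'
#' @param seed integer RNG seed; identical seeds give identical sets.
#' @return an `hf_params`.
#' @export
generate_random_param_set <- function(seed) {
  set.seed(seed)
  base_M <- rbind(c(0.977, 0.019, 0.004, 0.000),
                  c(0.008, 0.981, 0.010, 0.001),
                  c(0.000, 0.034, 0.960, 0.006),
                  c(0.000, 0.000, 0.055, 0.945))
  M <- matrix(0, 4, 4)
  for (g in 1:4) {
    alpha <- base_M[g, ] * 50
    pos <- alpha > 0
    draw <- numeric(4)
    draw[pos] <- stats::rgamma(sum(pos), alpha[pos], 1)
    M[g, ] <- draw / sum(draw)
  }
  mix_raw <- stats::rgamma(4, 1, 1)
  make_parameter_set(
    label = sprintf("random-%d", seed),
    cycle = cycle_spec(3, 10, stats::runif(1, 0, 0.08)),
    p_cv_death = c(control = stats::runif(1, 0, 0.3),
                   empagliflozin = stats::runif(1, 0, 0.3)),
    p_hosp = c(control = stats::runif(1, 0, 0.3),
               empagliflozin = stats::runif(1, 0, 0.3)),
    p_readmit = stats::runif(1, 0, 0.3),
    transition_matrix = M,
    mortality_bands = data.frame(age_from = c(65, 70, 75),
                                 age_to = c(69, 74, 79),
                                 p_cycle = sort(stats::runif(3, 0, 0.05))),
    utilities = sort(stats::runif(4), decreasing = TRUE),
    hosp_disutility = stats::runif(1, 0, 0.2),
    hosp_disutility_mode = sample(c("cycle_weight", "absolute_qaly"), 1),
    cost_standard = stats::runif(1, 1, 1e4),
    cost_drug = stats::runif(1, 1, 1e4),
    cost_hosp = stats::runif(1, 1, 1e4),
    initial_nyha_mix = mix_raw / sum(mix_raw))
}
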