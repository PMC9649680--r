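# Deterministic Markov cohort engine.
#
# Expanded state space (10 states): NYHA I-IV without the post-discharge
# tunnel flag, NYHA I-IV with it (hospitalised in the immediately preceding
# cycle, hence exposed to the readmission probability for exactly one cycle),
# and two absorbing states (CV death, non-CV death).

state_names <- c("I", "II", "III", "IV",
                 "I_post", "II_post", "III_post", "IV_post",
                 "cv_death", "non_cv_death")
live_idx <- 1:8
tunnel_idx <- 5:8

#' Per-cycle discount factor
#'
#' `(1 + r)^(-k * L)` where `k` is the cycle index (0 = model start), `r` the
#' annual discount rate, and `L` the cycle length in years.
#'
#' @param cycle_index integer cycle index (0-based; 0 gives factor 1).
#' @param spec a [cycle_spec()].
#' @return discount factor in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, spec) {
  stopifnot(all(cycle_index >= 0))
  (1 + spec$annual_discount_rate)^(-cycle_index * spec$cycle_length_years)
}

#' Per-cycle non-CV death probability at a given age
#'
#' Looks up the age band containing the (integer) current age; beyond the last
#' band either carries the last value forward or extrapolates log-linearly in
#' band-midpoint age, per the configured `extrapolation` mode.
#'
#' @param age current cohort age in years.
#' @param mortality the `mortality_non_cv` component of an `hf_params`.
#' @return per-cycle non-CV death probability.
#' @export
non_cv_death_prob <- function(age, mortality) {
  bands <- mortality$bands
  a <- floor(age + 1e-9)
  hit <- which(bands$age_from <= a & a <= bands$age_to)
  if (length(hit) == 1) return(bands$p_cycle[hit])
  if (a < bands$age_from[1]) return(bands$p_cycle[1])
  last <- nrow(bands)
  if (mortality$extrapolation == "carry_forward" || last < 2 ||
      any(bands$p_cycle <= 0)) {
    return(bands$p_cycle[last])
  }
  # log-linear in band midpoint age, fitted to all bands
  mid <- (bands$age_from + bands$age_to) / 2
  fit <- stats::lm(log(p_cycle) ~ mid, data = cbind(bands, mid = mid))
  min(1, exp(unname(stats::predict(fit, data.frame(mid = a)))))
}

arm_event_probs <- function(params, arm) {
  arm <- match.arg(arm, c("control", "empagliflozin"))
  list(p_cv = params$events[[arm]]$p_cv_death$value,
       p_hosp = params$events[[arm]]$p_hosp$value,
       p_readmit = params$events$p_readmit$value)
}

# Build the full 10x10 one-cycle transition matrix for one arm at one age,
# plus the per-state expected-hospitalisation coefficients.
# Event ordering within a cycle: competing death first (CV and non-CV risks
# combined under independence, deaths apportioned proportionally to the
# single-cause probabilities), then survivors redistribute over NYHA classes,
# then survivors are hospitalised (baseline probability from non-tunnel
# states, readmission probability from tunnel states); hospitalised fractions
# carry the tunnel flag into the next cycle.
build_cycle_matrix <- function(params, arm, age) {
  ev <- arm_event_probs(params, arm)
  p_ncv <- non_cv_death_prob(age, params$mortality_non_cv)
  p_cv <- ev$p_cv
  p_death <- 1 - (1 - p_cv) * (1 - p_ncv)
  denom <- p_cv + p_ncv
  share_cv <- if (denom > 0) p_cv / denom else 0
  surv <- 1 - p_death

  M <- params$transition_matrix
  P <- matrix(0, 10, 10, dimnames = list(state_names, state_names))
  event_coef <- numeric(10)
  for (s in live_idx) {
    g <- ((s - 1) %% 4) + 1
    h <- if (s %in% tunnel_idx) ev$p_readmit else ev$p_hosp
    P[s, 1:4] <- surv * M[g, ] * (1 - h)
    P[s, 5:8] <- surv * M[g, ] * h
    P[s, 9] <- p_death * share_cv
    P[s, 10] <- p_death * (1 - share_cv)
    event_coef[s] <- surv * h
  }
  P[9, 9] <- 1
  P[10, 10] <- 1
  list(P = P, event_coef = event_coef)
}

#' Advance the cohort by one cycle
#'
#' @param membership length-10 state-occupancy vector summing to 1 (order:
#'   NYHA I-IV, NYHA I-IV post-discharge, CV death, non-CV death).
#' @param params an `hf_params` object.
#' @param arm `"control"` or `"empagliflozin"`.
#' @param age cohort age at the start of the cycle, in years.
#' @return list with `membership` (updated, sums to 1) and `expected_events`
#'   (expected hospitalisations during the cycle).
#' @export
step_cycle <- function(membership, params, arm, age) {
  if (length(membership) != 10 || abs(sum(membership) - 1) > 1e-8) {
    stop("`membership` must be a length-10 vector summing to 1", call. = FALSE)
  }
  cm <- build_cycle_matrix(params, arm, age)
  list(membership = as.numeric(membership %*% cm$P),
       expected_events = sum(membership * cm$event_coef))
}

#' Run the deterministic cohort trace for one arm
#'
#' Starts the whole cohort in the configured initial NYHA mix (non-tunnel),
#' ages it by one cycle length per cycle, and records per-cycle occupancy and
#' expected hospitalisation events over the full horizon.
#'
#' @inheritParams step_cycle
#' @return a `cycle_trace`: data.frame with one row per cycle node 0..N,
#'   columns `cycle`, `age`, the 10 state occupancies, `events` (expected
#'   hospitalisations during the cycle ending at that node; 0 for node 0),
#'   and `alive`.
#' @export
run_cohort <- function(params, arm) {
  spec <- params$cycle
  n <- spec$n_cycles
  m <- c(params$population$initial_nyha_mix, rep(0, 6))
  ages <- params$population$start_age + (seq_len(n) - 1) * spec$cycle_length_years

  occ <- matrix(0, n + 1, 10, dimnames = list(NULL, state_names))
  occ[1, ] <- m
  events <- numeric(n + 1)

  # cache the cycle matrix per mortality band (the only age-varying input)
  cache <- list()
  for (k in seq_len(n)) {
    key <- sprintf("%.6g", non_cv_death_prob(ages[k], params$mortality_non_cv))
    if (is.null(cache[[key]])) cache[[key]] <- build_cycle_matrix(params, arm, ages[k])
    cm <- cache[[key]]
    events[k + 1] <- sum(occ[k, ] * cm$event_coef)
    occ[k + 1, ] <- occ[k, ] %*% cm$P
  }

  out <- data.frame(cycle = 0:n,
                    age = params$population$start_age + (0:n) * spec$cycle_length_years,
                    occ, events = events,
                    alive = rowSums(occ[, live_idx, drop = FALSE]),
                    check.names = FALSE)
  class(out) <- c("cycle_trace", "data.frame")
  attr(out, "arm") <- arm
  out
}

#' Accumulate discounted, half-cycle-corrected totals from a trace
#'
#' State-occupancy payoffs (NYHA utilities; per-cycle therapy and drug cost
#' while alive) are integrated with the trapezoid rule on the discounted
#' payoff stream — the average of adjacent cycle nodes, each at its own
#' discount factor — which is the half-cycle correction. Event payoffs
#' (hospitalisation cost and the 0.1 utility decrement per admission) are
#' attached to the cycle in which they occur and discounted at that cycle's
#' end-of-cycle factor.
#'
#' The hospitalisation disutility mode is `"cycle_weight"` (decrement applied
#' for one cycle length: QALY loss `0.1 * L * events`) or `"absolute_qaly"`
#' (fixed QALY loss `0.1 * events`).
#'
#' @param trace a `cycle_trace` from [run_cohort()].
#' @param params the `hf_params` used to produce it.
#' @param arm `"control"` or `"empagliflozin"` (drug cost accrues only in the
#'   empagliflozin arm).
#' @return an `arm_result` list: `total_discounted_cost`,
#'   `total_discounted_qalys`, undiscounted counterparts, `life_years`,
#'   `expected_cv_deaths`, `expected_hospitalisations`.
#' @export
accumulate <- function(trace, params, arm) {
  arm <- match.arg(arm, c("control", "empagliflozin"))
  spec <- params$cycle
  L <- spec$cycle_length_years
  n <- spec$n_cycles
  stopifnot(nrow(trace) == n + 1)

  d <- discount_factor(0:n, spec)
  u <- vapply(params$utilities$by_nyha, `[[`, numeric(1), "value")
  occ_live <- as.matrix(trace[, state_names[live_idx]])
  util_node <- as.numeric(occ_live %*% rep(u, 2))   # utility-weighted occupancy
  alive <- trace$alive
  events <- trace$events

  trapz <- function(x) sum((x[-1] + x[-(n + 1)]) / 2)

  per_cycle_cost <- params$costs$standard_therapy_per_cycle$value +
    if (arm == "empagliflozin") params$costs$drug_per_cycle$value else 0
  hosp_cost <- params$costs$hosp_cost_per_event$value
  hd <- params$utilities$hosp_disutility$value
  ev_qaly_loss <- if (params$utilities$hosp_disutility_mode == "cycle_weight") {
    hd * L * events
  } else {
    hd * events
  }

  qalys_disc <- L * trapz(d * util_node) - sum(d * ev_qaly_loss)
  qalys_undisc <- L * trapz(util_node) - sum(ev_qaly_loss)
  cost_disc <- per_cycle_cost * trapz(d * alive) + hosp_cost * sum(d * events)
  cost_undisc <- per_cycle_cost * trapz(alive) + hosp_cost * sum(events)

  structure(
    list(total_discounted_cost = cost_disc,
         total_discounted_qalys = qalys_disc,
         total_undiscounted_cost = cost_undisc,
         total_undiscounted_qalys = qalys_undisc,
         life_years = L * trapz(alive),
         expected_cv_deaths = trace$cv_death[n + 1],
         expected_hospitalisations = sum(events)),
    class = "arm_result")
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate()].
#'
#' @inheritParams step_cycle
#' @return an `arm_result`.
#' @export
run_arm <- function(params, arm) {
  accumulate(run_cohort(params, arm), params, arm)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle node with all expanded-state occupancies, expected
#' events, and discounted/undiscounted per-cycle cost and QALYs.
#'
#' @param trace a `cycle_trace`.
#' @param params the `hf_params` used to produce it.
#' @param arm treatment arm.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, params, arm, path) {
  spec <- params$cycle
  L <- spec$cycle_length_years
  d <- discount_factor(trace$cycle, spec)
  u <- vapply(params$utilities$by_nyha, `[[`, numeric(1), "value")
  util_node <- as.numeric(as.matrix(trace[, state_names[live_idx]]) %*% rep(u, 2))
  per_cycle_cost <- params$costs$standard_therapy_per_cycle$value +
    if (arm == "empagliflozin") params$costs$drug_per_cycle$value else 0
  hd <- params$utilities$hosp_disutility$value
  ev_loss <- if (params$utilities$hosp_disutility_mode == "cycle_weight") {
    hd * L * trace$events
  } else {
    hd * trace$events
  }
  out <- cbind(trace,
               discount = d,
               qaly_node = L * util_node,
               qaly_event_loss = ev_loss,
               cost_node = per_cycle_cost * trace$alive,
               cost_events = params$costs$hosp_cost_per_event$value * trace$events)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
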