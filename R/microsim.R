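# Patient-level microsimulation: an independent Monte-Carlo realisation of
# the same per-cycle event logic as the cohort engine, used to cross-check
# it. Implemented with per-patient Bernoulli/categorical draws and
# per-patient payoff arithmetic — no occupancy-vector algebra — so agreement
# with the cohort trace is evidence, not tautology.

#' Simulate individual patient trajectories
#'
#' Each patient starts in the initial NYHA mix (non-tunnel) and per cycle:
#' dies with the combined CV/non-CV probability (cause drawn proportionally
#' to the single-cause probabilities); survivors draw a new NYHA class from
#' the transition-matrix row and a hospitalisation event (readmission
#' probability while in the post-discharge tunnel, baseline otherwise), which
#' sets the tunnel flag for the next cycle. Costs and QALYs accrue per
#' patient under exactly the accumulation rules of [accumulate()]:
#' trapezoidal half-cycle weighting of state occupancy at per-node discount
#' factors, event payoffs at the end-of-cycle factor.
#'
#' @param params an `hf_params`.
#' @param arm `"control"` or `"empagliflozin"`.
#' @param n number of simulated patients (>= 1).
#' @param seed integer RNG seed.
#' @param trajectories if `TRUE`, also return a per-patient-cycle data.frame
#'   (patient, cycle, nyha, tunnel, alive, event) for debugging/export.
#' @return a `microsim_summary` list: `n`, per-patient means and standard
#'   errors of discounted cost and QALYs, mean hospitalisation events, the
#'   fraction of CV deaths, and (optionally) `trajectories`.
#' @export
simulate_patients <- function(params, arm, n, seed, trajectories = FALSE) {
  stopifnot(n >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  arm <- match.arg(arm, c("control", "empagliflozin"))
  set.seed(seed)

  spec <- params$cycle
  L <- spec$cycle_length_years
  ncyc <- spec$n_cycles
  ev <- arm_event_probs(params, arm)
  M <- params$transition_matrix
  u <- vapply(params$utilities$by_nyha, `[[`, numeric(1), "value")
  per_cycle_cost <- params$costs$standard_therapy_per_cycle$value +
    if (arm == "empagliflozin") params$costs$drug_per_cycle$value else 0
  hosp_cost <- params$costs$hosp_cost_per_event$value
  hd <- params$utilities$hosp_disutility$value
  cw <- params$utilities$hosp_disutility_mode == "cycle_weight"
  d <- discount_factor(0:ncyc, spec)

  nyha <- sample.int(4, n, replace = TRUE,
                     prob = params$population$initial_nyha_mix)
  tunnel <- rep(FALSE, n)
  alive <- rep(TRUE, n)
  cause <- rep(NA_character_, n)
  qaly <- cost <- n_events <- numeric(n)

  # node-0 half of the first trapezoid
  prev_u <- u[nyha]
  prev_alive_num <- rep(1, n)

  traj <- if (trajectories) vector("list", ncyc) else NULL

  for (k in seq_len(ncyc)) {
    age <- params$population$start_age + (k - 1) * L
    p_ncv <- non_cv_death_prob(age, params$mortality_non_cv)
    p_death <- 1 - (1 - ev$p_cv) * (1 - p_ncv)
    share_cv <- if (ev$p_cv + p_ncv > 0) ev$p_cv / (ev$p_cv + p_ncv) else 0

    idx <- which(alive)
    event_now <- rep(FALSE, n)
    if (length(idx)) {
      dies <- stats::runif(length(idx)) < p_death
      died_idx <- idx[dies]
      if (length(died_idx)) {
        cv <- stats::runif(length(died_idx)) < share_cv
        cause[died_idx] <- ifelse(cv, "cv", "non_cv")
        alive[died_idx] <- FALSE
      }
      surv_idx <- idx[!dies]
      if (length(surv_idx)) {
        # categorical NYHA move, drawn class-by-class from the matrix rows
        from <- nyha[surv_idx]
        for (g in 1:4) {
          grp <- surv_idx[from == g]
          if (length(grp)) {
            nyha[grp] <- sample.int(4, length(grp), replace = TRUE,
                                    prob = M[g, ])
          }
        }
        p_ev <- ifelse(tunnel[surv_idx], ev$p_readmit, ev$p_hosp)
        hosp <- stats::runif(length(surv_idx)) < p_ev
        event_now[surv_idx] <- hosp
        tunnel[surv_idx] <- hosp
        n_events[surv_idx] <- n_events[surv_idx] + hosp
      }
    }

    cur_u <- ifelse(alive, u[nyha], 0)
    cur_alive_num <- as.numeric(alive)

    qaly <- qaly + L * (d[k] * prev_u + d[k + 1] * cur_u) / 2 -
      d[k + 1] * hd * (if (cw) L else 1) * event_now
    cost <- cost + per_cycle_cost * (d[k] * prev_alive_num +
                                     d[k + 1] * cur_alive_num) / 2 +
      hosp_cost * d[k + 1] * event_now

    prev_u <- cur_u
    prev_alive_num <- cur_alive_num

    if (trajectories) {
      traj[[k]] <- data.frame(patient = seq_len(n), cycle = k, nyha = nyha,
                              tunnel = tunnel, alive = alive,
                              event = event_now)
    }
  }

  out <- structure(
    list(n = n, arm = arm, seed = seed,
         mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
         mean_qalys = mean(qaly), se_qalys = stats::sd(qaly) / sqrt(n),
         mean_events = mean(n_events),
         se_events = stats::sd(n_events) / sqrt(n),
         frac_cv_death = mean(!is.na(cause) & cause == "cv")),
    class = "microsim_summary")
  if (trajectories) out$trajectories <- do.call(rbind, traj)
  out
}

#' @export
print.microsim_summary <- function(x, ...) {
  cat(sprintf("<microsim_summary> %s arm, n = %d\n", x$arm, x$n))
  cat(sprintf("  discounted cost  %.2f (SE %.3f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  discounted QALYs %.4f (SE %.5f)\n", x$mean_qalys, x$se_qalys))
  cat(sprintf("  hospitalisations/patient %.4f; CV-death fraction %.4f\n",
              x$mean_events, x$frac_cv_death))
  invisible(x)
}
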