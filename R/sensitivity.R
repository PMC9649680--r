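# One-way sensitivity analysis, probabilistic sensitivity analysis with
# beta/gamma/Dirichlet sampling, CEAC construction, and scenario runner.

#' Registry of scalar parameters varied in sensitivity analyses
#'
#' @param params an `hf_params`.
#' @return data.frame with `name`, `value`, `low`, `high`, `dist`.
#' @export
sa_parameter_table <- function(params) {
  e <- params$events
  u <- params$utilities
  co <- params$costs
  rows <- list(
    p_cv_death_control = e$control$p_cv_death,
    p_cv_death_empagliflozin = e$empagliflozin$p_cv_death,
    p_hosp_control = e$control$p_hosp,
    p_hosp_empagliflozin = e$empagliflozin$p_hosp,
    p_readmit = e$p_readmit,
    utility_I = u$by_nyha$I,
    utility_II = u$by_nyha$II,
    utility_III = u$by_nyha$III,
    utility_IV = u$by_nyha$IV,
    hosp_disutility = u$hosp_disutility,
    cost_standard_therapy = co$standard_therapy_per_cycle,
    cost_drug = co$drug_per_cycle,
    cost_hospitalisation = co$hosp_cost_per_event,
    discount_rate = params$discount)
  data.frame(name = names(rows),
             value = vapply(rows, `[[`, numeric(1), "value"),
             low = vapply(rows, `[[`, numeric(1), "low"),
             high = vapply(rows, `[[`, numeric(1), "high"),
             dist = vapply(rows, `[[`, character(1), "dist"),
             row.names = NULL)
}

#' Return a copy of a parameter set with one scalar parameter replaced
#'
#' @param params an `hf_params`.
#' @param name a parameter name from [sa_parameter_table()].
#' @param value the replacement value.
#' @return the modified `hf_params`.
#' @export
set_model_param <- function(params, name, value) {
  p <- params
  switch(name,
    p_cv_death_control = p$events$control$p_cv_death$value <- value,
    p_cv_death_empagliflozin = p$events$empagliflozin$p_cv_death$value <- value,
    p_hosp_control = p$events$control$p_hosp$value <- value,
    p_hosp_empagliflozin = p$events$empagliflozin$p_hosp$value <- value,
    p_readmit = p$events$p_readmit$value <- value,
    utility_I = p$utilities$by_nyha$I$value <- value,
    utility_II = p$utilities$by_nyha$II$value <- value,
    utility_III = p$utilities$by_nyha$III$value <- value,
    utility_IV = p$utilities$by_nyha$IV$value <- value,
    hosp_disutility = p$utilities$hosp_disutility$value <- value,
    cost_standard_therapy = p$costs$standard_therapy_per_cycle$value <- value,
    cost_drug = p$costs$drug_per_cycle$value <- value,
    cost_hospitalisation = p$costs$hosp_cost_per_event$value <- value,
    discount_rate = {
      p$cycle$annual_discount_rate <- value
      p$discount$value <- value
    },
    stop("unknown model parameter: ", name, call. = FALSE))
  p
}

icer_for <- function(params) {
  inc <- compute_incremental(run_arm(params, "empagliflozin"),
                             run_arm(params, "control"),
                             params$wtp)
  # raw ratio so that dominant draws still yield a finite tornado endpoint
  inc$delta_cost / inc$delta_qalys
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the base case with each parameter in turn set to the lower and upper
#' endpoint of its published range, all else fixed, and reports the ICER at
#' each endpoint and the swing `|ICER_high - ICER_low|`, sorted widest first.
#'
#' @param params an `hf_params`.
#' @return data.frame with `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `swing`, ordered by decreasing swing.
#' @export
one_way_sa <- function(params) {
  tab <- sa_parameter_table(params)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    data.frame(parameter = r$name, low = r$low, high = r$high,
               icer_low = icer_for(set_model_param(params, r$name, r$low)),
               icer_high = icer_for(set_model_param(params, r$name, r$high)))
  })
  out <- do.call(rbind, res)
  out$swing <- abs(out$icer_high - out$icer_low)
  out[order(-out$swing), , drop = FALSE]
}

#' Fit a sampling distribution to a point estimate and range
#'
#' Ranges are read as 95% intervals, so `sd = (high - low) / (2 * 1.96)`.
#' Beta and gamma are fitted by the method of moments around the point
#' estimate; a zero-width range, or beta moments that are infeasible
#' (`sd^2 >= mean * (1 - mean)`), yields a point mass (with a warning in the
#' infeasible case).
#'
#' @param point point estimate (the distribution mean).
#' @param range numeric pair `c(low, high)`.
#' @param kind `"beta"`, `"gamma"`, or `"fixed"`.
#' @return a `sa_dist` list with a `sample(n)` function and the fitted
#'   parameters.
#' @export
parameterise_distribution <- function(point, range, kind = c("beta", "gamma", "fixed")) {
  kind <- match.arg(kind)
  stopifnot(length(range) == 2, range[1] <= point, point <= range[2])
  s <- (range[2] - range[1]) / (2 * stats::qnorm(0.975))
  if (s == 0 || kind == "fixed") {
    return(structure(list(kind = "point_mass", mean = point, sd = 0,
                          sample = function(n) rep(point, n)),
                     class = "sa_dist"))
  }
  if (kind == "beta") {
    if (point <= 0 || point >= 1 || s^2 >= point * (1 - point)) {
      warning(sprintf(
        "beta moments infeasible for mean %.4g, sd %.4g; using a point mass",
        point, s), call. = FALSE)
      return(structure(list(kind = "point_mass", mean = point, sd = 0,
                            sample = function(n) rep(point, n)),
                       class = "sa_dist"))
    }
    a <- point * (point * (1 - point) / s^2 - 1)
    b <- a * (1 - point) / point
    structure(list(kind = "beta", mean = point, sd = s, shape1 = a, shape2 = b,
                   sample = function(n) stats::rbeta(n, a, b)),
              class = "sa_dist")
  } else {
    shape <- (point / s)^2
    rate <- point / s^2
    structure(list(kind = "gamma", mean = point, sd = s, shape = shape,
                   rate = rate,
                   sample = function(n) stats::rgamma(n, shape, rate)),
              class = "sa_dist")
  }
}

#' Sample NYHA transition matrices row-wise from Dirichlet distributions
#'
#' Each row uses concentration `row_probabilities * ess`; structural zeros
#' stay exactly zero.
#'
#' @param M base 4x4 transition matrix.
#' @param n number of samples.
#' @param ess Dirichlet effective sample size (default 1000); a non-finite or
#'   non-positive value keeps every sampled matrix fixed at `M`.
#' @return array `c(n, 4, 4)` of sampled matrices (each row sums to 1).
#' @export
sample_transition_matrices <- function(M, n, ess = 1000) {
  out <- array(0, c(n, 4, 4))
  if (!is.finite(ess) || ess <= 0) {
    for (i in seq_len(n)) out[i, , ] <- M
    return(out)
  }
  for (g in 1:4) {
    alpha <- M[g, ] * ess
    pos <- alpha > 0
    draws <- matrix(0, n, 4)
    for (j in which(pos)) draws[, j] <- stats::rgamma(n, alpha[j], 1)
    draws <- draws / rowSums(draws)
    out[, g, ] <- draws
  }
  out
}

psa_sampled_names <- c("p_cv_death_control", "p_cv_death_empagliflozin",
                       "p_hosp_control", "p_hosp_empagliflozin", "p_readmit",
                       "utility_I", "utility_II", "utility_III", "utility_IV",
                       "hosp_disutility",
                       "cost_standard_therapy", "cost_drug",
                       "cost_hospitalisation")

#' Probabilistic sensitivity analysis
#'
#' Samples every distribution-tagged parameter (event probabilities,
#' utilities and the hospitalisation disutility magnitude as beta; costs as
#' gamma; NYHA transition rows as Dirichlet), reruns both arms per draw, and
#' records the incremental cost/QALY pair. Utility draws violating the
#' severity ordering `u(I) >= u(II) >= u(III) >= u(IV)` are resampled.
#' Discount rate and non-CV mortality are held fixed. Identical seeds give
#' identical draws.
#'
#' @param params an `hf_params`.
#' @param n number of draws (default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @return a `psa_result` data.frame with `draw`, `delta_cost`,
#'   `delta_qalys`; the sampled parameter values are attached as attribute
#'   `"samples"` and `attr(, "resampled_utility_draws")` counts ordering
#'   rejections.
#' @export
run_psa <- function(params, n = 1000, seed) {
  if (missing(seed)) stop("`seed` is required for a reproducible PSA", call. = FALSE)
  set.seed(seed)

  tab <- sa_parameter_table(params)
  rownames(tab) <- tab$name
  dists <- lapply(psa_sampled_names, function(nm) {
    r <- tab[nm, ]
    parameterise_distribution(r$value, c(r$low, r$high),
                              if (r$dist == "gamma") "gamma" else "beta")
  })
  names(dists) <- psa_sampled_names

  samples <- vapply(dists, function(d) d$sample(n), numeric(n))
  if (n == 1) samples <- matrix(samples, 1, dimnames = list(NULL, psa_sampled_names))

  # enforce the utility severity ordering by resampling violating draws
  ucols <- paste0("utility_", c("I", "II", "III", "IV"))
  resampled <- 0L
  repeat {
    U <- samples[, ucols, drop = FALSE]
    bad <- which(U[, 1] < U[, 2] | U[, 2] < U[, 3] | U[, 3] < U[, 4])
    if (!length(bad)) break
    resampled <- resampled + length(bad)
    for (cc in ucols) samples[bad, cc] <- dists[[cc]]$sample(length(bad))
  }

  tms <- sample_transition_matrices(params$transition_matrix, n,
                                    ess = params$psa$dirichlet_ess)

  dc <- de <- numeric(n)
  for (i in seq_len(n)) {
    p_i <- params
    for (nm in psa_sampled_names) p_i <- set_model_param(p_i, nm, samples[i, nm])
    M <- tms[i, , ]
    dimnames(M) <- dimnames(params$transition_matrix)
    p_i$transition_matrix <- M
    inc <- compute_incremental(run_arm(p_i, "empagliflozin"),
                               run_arm(p_i, "control"), p_i$wtp)
    dc[i] <- inc$delta_cost
    de[i] <- inc$delta_qalys
  }

  out <- data.frame(draw = seq_len(n), delta_cost = dc, delta_qalys = de)
  class(out) <- c("psa_result", "data.frame")
  attr(out, "samples") <- samples
  attr(out, "resampled_utility_draws") <- resampled
  attr(out, "seed") <- seed
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability cost-effective is the
#' fraction of PSA draws with strictly positive net monetary benefit (ties
#' count as not cost-effective).
#'
#' @param draws a `psa_result` (or data.frame with `delta_cost`,
#'   `delta_qalys`).
#' @param wtp_grid vector of WTP values in USD/QALY.
#' @return data.frame with `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (NROW(draws) == 0) stop("`draws` must be non-empty", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * draws$delta_qalys - draws$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Apply a scenario's overrides to a parameter set
#'
#' Recognised overrides: `drug_per_cycle` (USD), `hosp_cost_per_event` (USD),
#' `horizon_years`.
#'
#' @param params an `hf_params`.
#' @param scenario named list with `name` and overrides.
#' @return modified `hf_params`.
#' @export
apply_scenario <- function(params, scenario) {
  p <- params
  for (field in setdiff(names(scenario), "name")) {
    val <- scenario[[field]]
    p <- switch(field,
      drug_per_cycle = set_model_param(p, "cost_drug", val),
      hosp_cost_per_event = set_model_param(p, "cost_hospitalisation", val),
      horizon_years = {
        p$cycle <- cycle_spec(p$cycle$cycle_length_months, val,
                              p$cycle$annual_discount_rate)
        p
      },
      stop("unknown scenario override: ", field, call. = FALSE))
  }
  p
}

#' Run the configured scenario analyses
#'
#' Applies each scenario's overrides, reruns both arms, and reports the ICER
#' from unrounded increments. The base case is included as the first row.
#'
#' @param params an `hf_params`.
#' @param scenarios list of scenario specs; defaults to those bundled in the
#'   configuration.
#' @return data.frame with `scenario`, `delta_cost`, `delta_qalys`, `icer`.
#' @export
run_scenarios <- function(params, scenarios = params$scenarios) {
  all <- c(list(list(name = "base_case")), scenarios)
  rows <- lapply(all, function(sc) {
    p <- apply_scenario(params, sc)
    inc <- compute_incremental(run_arm(p, "empagliflozin"),
                               run_arm(p, "control"), p$wtp)
    data.frame(scenario = sc$name, delta_cost = inc$delta_cost,
               delta_qalys = inc$delta_qalys,
               icer = inc$delta_cost / inc$delta_qalys)
  })
  do.call(rbind, rows)
}
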