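#' Convert a trial-level cumulative incidence to a per-cycle probability
#'
#' Assumes a constant event hazard over the trial follow-up: the incidence
#' `S_inc` observed over `followup` months implies a monthly rate
#' `r = -log(1 - S_inc) / followup`, which converts to a probability over one
#' model cycle as `P = 1 - exp(-r * cycle_length)`.
#'
#' @param incidence cumulative incidence over the follow-up, in `[0, 1)`.
#' @param followup follow-up duration in months (> 0).
#' @param cycle_length model cycle length in months (default 3).
#' @return per-cycle event probability in `[0, 1)`.
#' @examples
#' # EMPEROR-Reduced control-arm CV death: 10.8% over 16 months -> 0.0212/cycle
#' cumulative_incidence_to_cycle_prob(0.108, 16)
#' @export
cumulative_incidence_to_cycle_prob <- function(incidence, followup, cycle_length = 3) {
  if (any(incidence < 0) || any(incidence >= 1)) {
    stop("`incidence` must be in [0, 1)", call. = FALSE)
  }
  if (any(followup <= 0)) stop("`followup` must be > 0", call. = FALSE)
  if (any(cycle_length <= 0)) stop("`cycle_length` must be > 0", call. = FALSE)
  rate <- -log(1 - incidence) / followup
  1 - exp(-rate * cycle_length)
}

#' Convert a short-interval risk, read as a monthly rate, to a per-cycle probability
#'
#' For 30-day readmission risks the risk figure is treated directly as a
#' monthly event rate: `P = 1 - exp(-rate * cycle_length)`.
#'
#' @param rate_per_month monthly event rate (>= 0).
#' @param cycle_length cycle length in months (default 3).
#' @return per-cycle probability in `[0, 1)`.
#' @examples
#' short_rate_to_cycle_prob(0.134, 3) # 30-day HF readmission risk -> 0.331
#' @export
short_rate_to_cycle_prob <- function(rate_per_month, cycle_length = 3) {
  if (any(rate_per_month < 0)) stop("`rate_per_month` must be >= 0", call. = FALSE)
  if (any(cycle_length <= 0)) stop("`cycle_length` must be > 0", call. = FALSE)
  1 - exp(-rate_per_month * cycle_length)
}

#' Probability -> rate -> probability round trip over the same interval
#'
#' Consistency check for the two hazard conversions: recovers `p` exactly
#' (up to floating error) for any `p` in `[0, 1)`.
#'
#' @param p probability in `[0, 1)`.
#' @param T interval length in months.
#' @return the probability recovered after converting to a rate and back.
#' @export
prob_roundtrip <- function(p, T) {
  if (any(p < 0) || any(p >= 1)) stop("`p` must be in [0, 1)", call. = FALSE)
  rate <- -log(1 - p) / T
  1 - exp(-rate * T)
}

# ---- parameter-set construction and validation -------------------------------

nyha_levels <- c("I", "II", "III", "IV")

#' Cycle and discounting settings
#'
#' @param cycle_length_months cycle length in months.
#' @param horizon_years time horizon in years; must be a whole number of cycles.
#' @param annual_discount_rate annual discount rate as a fraction in `[0, 1)`.
#' @return a `cycle_spec` list.
#' @export
cycle_spec <- function(cycle_length_months = 3, horizon_years = 10,
                       annual_discount_rate = 0.05) {
  stopifnot(cycle_length_months > 0, horizon_years > 0,
            annual_discount_rate >= 0, annual_discount_rate < 1)
  n_cycles <- horizon_years * 12 / cycle_length_months
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("`horizon_years` must be an integer number of cycles", call. = FALSE)
  }
  structure(
    list(cycle_length_months = cycle_length_months,
         cycle_length_years = cycle_length_months / 12,
         horizon_years = horizon_years,
         n_cycles = as.integer(round(n_cycles)),
         annual_discount_rate = annual_discount_rate),
    class = "cycle_spec")
}

new_param <- function(value, range = c(value, value), dist = "none") {
  if (length(range) != 2 || range[1] > value || value > range[2]) {
    stop("parameter range must satisfy lower <= value <= upper", call. = FALSE)
  }
  list(value = value, low = range[1], high = range[2], dist = dist)
}

validate_transition_matrix <- function(M) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4))) {
    stop("transition matrix must be 4x4 (NYHA I-IV)", call. = FALSE)
  }
  if (any(M < 0) || any(M > 1)) {
    stop("transition matrix entries must be in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9)) {
    stop(sprintf("transition matrix row %d sums to %.6f, not 1",
                 which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))]),
         call. = FALSE)
  }
  # structurally impossible jumps in severity
  forb <- rbind(c(1, 4), c(3, 1), c(4, 1), c(4, 2))
  bad <- M[forb] != 0
  if (any(bad)) {
    stop(sprintf("structurally forbidden transition %s->%s must be exactly 0",
                 nyha_levels[forb[which(bad)[1], 1]],
                 nyha_levels[forb[which(bad)[1], 2]]),
         call. = FALSE)
  }
  dimnames(M) <- list(nyha_levels, nyha_levels)
  M
}

#' Validate a parameter set
#'
#' Enforces every structural invariant: probabilities in `[0,1]`, transition
#' rows summing to 1 with the structural zeros of the published NYHA matrix,
#' ordered utilities, non-negative costs, contiguous non-decreasing mortality
#' bands, and an initial NYHA mix summing to 1.
#'
#' @param params an `hf_params` object.
#' @return `params`, invisibly, if valid; otherwise a descriptive error.
#' @export
validate_parameter_set <- function(params) {
  p <- params
  stopifnot(inherits(p$cycle, "cycle_spec"))
  for (arm in c("control", "empagliflozin")) {
    for (ev in c("p_cv_death", "p_hosp")) {
      pr <- p$events[[arm]][[ev]]
      if (pr$value < 0 || pr$value > 1 || pr$low < 0 || pr$high > 1) {
        stop(sprintf("events.%s.%s out of [0, 1]", arm, ev), call. = FALSE)
      }
    }
  }
  if (p$events$p_readmit$value < 0 || p$events$p_readmit$value > 1) {
    stop("events.p_readmit out of [0, 1]", call. = FALSE)
  }
  p$transition_matrix <- validate_transition_matrix(p$transition_matrix)
  mort <- p$mortality_non_cv$bands
  if (!all(c("age_from", "age_to", "p_cycle") %in% names(mort))) {
    stop("mortality_non_cv$bands needs age_from, age_to, p_cycle", call. = FALSE)
  }
  if (nrow(mort) > 1 && any(mort$age_from[-1] != mort$age_to[-nrow(mort)] + 1)) {
    stop("mortality bands must be contiguous", call. = FALSE)
  }
  if (any(mort$p_cycle < 0 | mort$p_cycle > 1) || is.unsorted(mort$p_cycle)) {
    stop("mortality probabilities must be in [0,1] and non-decreasing with age",
         call. = FALSE)
  }
  u <- vapply(p$utilities$by_nyha, `[[`, numeric(1), "value")
  if (any(u < 0) || any(u > 1) || is.unsorted(rev(u))) {
    stop("utilities must satisfy 0 <= u(IV) <= u(III) <= u(II) <= u(I) <= 1",
         call. = FALSE)
  }
  if (p$utilities$hosp_disutility$value < 0) {
    stop("hosp_disutility magnitude must be >= 0", call. = FALSE)
  }
  if (!p$utilities$hosp_disutility_mode %in% c("cycle_weight", "absolute_qaly")) {
    stop("hosp_disutility_mode must be 'cycle_weight' or 'absolute_qaly'",
         call. = FALSE)
  }
  costs <- vapply(p$costs, `[[`, numeric(1), "value")
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  mix <- p$population$initial_nyha_mix
  if (length(mix) != 4 || any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("population.initial_nyha_mix must be 4 non-negative fractions summing to 1",
         call. = FALSE)
  }
  if (!is.null(p$wtp) && p$wtp[1] >= p$wtp[2]) {
    stop("wtp thresholds must satisfy lower < upper", call. = FALSE)
  }
  invisible(params)
}

#' Load a model parameter set from a YAML configuration file
#'
#' Reads one population's full parameterisation (cycle settings, trial-level
#' event inputs, NYHA transition matrix, non-CV mortality bands, utilities,
#' costs, WTP thresholds, scenario definitions), converts trial-level inputs
#' to per-cycle probabilities, and validates every invariant.
#'
#' Event entries may give either a trial-level `incidence` with
#' `followup_months` (converted with [cumulative_incidence_to_cycle_prob()]),
#' a `rate_per_month` (converted with [short_rate_to_cycle_prob()]), or a
#' direct per-cycle `value`.
#'
#' @param config_source path to a YAML file, or an already-parsed list.
#' @return a validated `hf_params` object.
#' @seealso [hf_config_path()] for the bundled HFrEF/HFpEF configurations.
#' @export
load_parameter_set <- function(config_source) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("config file not found: ", config_source, call. = FALSE)
    }
    yaml::read_yaml(config_source)
  } else {
    config_source
  }

  cyc <- cfg$cycle
  spec <- cycle_spec(cycle_length_months = cyc$length_months %||% 3,
                     horizon_years = cyc$horizon_years %||% 10,
                     annual_discount_rate = cyc$annual_discount_rate %||% 0.05)

  read_event <- function(e, what) {
    val <- if (!is.null(e$value)) {
      e$value
    } else if (!is.null(e$incidence)) {
      cumulative_incidence_to_cycle_prob(e$incidence, e$followup_months,
                                         spec$cycle_length_months)
    } else if (!is.null(e$rate_per_month)) {
      short_rate_to_cycle_prob(e$rate_per_month, spec$cycle_length_months)
    } else {
      stop("event '", what, "' needs value, incidence, or rate_per_month",
           call. = FALSE)
    }
    rng <- if (!is.null(e$range)) unlist(e$range) else c(val, val)
    new_param(val, rng, e$dist %||% "beta")
  }

  events <- list(
    control = list(
      p_cv_death = read_event(cfg$events$control$cv_death, "control.cv_death"),
      p_hosp = read_event(cfg$events$control$hospitalisation,
                          "control.hospitalisation")),
    empagliflozin = list(
      p_cv_death = read_event(cfg$events$empagliflozin$cv_death,
                              "empagliflozin.cv_death"),
      p_hosp = read_event(cfg$events$empagliflozin$hospitalisation,
                          "empagliflozin.hospitalisation")),
    p_readmit = read_event(cfg$events$readmission, "readmission"))

  M <- do.call(rbind, lapply(cfg$transition_matrix, unlist))
  dimnames(M) <- list(nyha_levels, nyha_levels)

  mort_cfg <- cfg$mortality_non_cv
  bands <- do.call(rbind, lapply(mort_cfg$bands, function(b) {
    data.frame(age_from = b$age_from, age_to = b$age_to, p_cycle = b$p_cycle)
  }))
  mortality <- list(bands = bands,
                    extrapolation = mort_cfg$extrapolation %||% "carry_forward")
  if (!mortality$extrapolation %in% c("carry_forward", "log_linear")) {
    stop("mortality_non_cv.extrapolation must be carry_forward or log_linear",
         call. = FALSE)
  }

  ut <- cfg$utilities
  by_nyha <- lapply(nyha_levels, function(g) {
    u <- ut$by_nyha[[g]]
    new_param(u$value, if (!is.null(u$range)) unlist(u$range) else c(u$value, u$value),
              u$dist %||% "beta")
  })
  names(by_nyha) <- nyha_levels
  hd <- ut$hosp_disutility
  utilities <- list(
    by_nyha = by_nyha,
    # stored as a positive magnitude; Table-style negative values are sign-flipped
    hosp_disutility = new_param(abs(hd$value),
                                sort(abs(if (!is.null(hd$range)) unlist(hd$range)
                                         else c(hd$value, hd$value))),
                                hd$dist %||% "beta"),
    hosp_disutility_mode = ut$hosp_disutility_mode %||% "cycle_weight")

  cs <- cfg$costs
  read_cost <- function(cc) {
    new_param(cc$value, if (!is.null(cc$range)) unlist(cc$range) else c(cc$value, cc$value),
              cc$dist %||% "gamma")
  }
  costs <- list(standard_therapy_per_cycle = read_cost(cs$standard_therapy_per_cycle),
                drug_per_cycle = read_cost(cs$drug_per_cycle),
                hosp_cost_per_event = read_cost(cs$hosp_cost_per_event))

  pop <- cfg$population
  mix <- unlist(pop$initial_nyha_mix)[nyha_levels]
  population <- list(label = pop$label %||% "HFrEF",
                     start_age = pop$start_age %||% 65,
                     initial_nyha_mix = mix)

  params <- structure(
    list(cycle = spec,
         events = events,
         transition_matrix = M,
         mortality_non_cv = mortality,
         utilities = utilities,
         costs = costs,
         population = population,
         discount = new_param(spec$annual_discount_rate,
                              if (!is.null(cyc$discount_range))
                                unlist(cyc$discount_range)
                              else c(spec$annual_discount_rate,
                                     spec$annual_discount_rate),
                              "none"),
         wtp = unlist(cfg$wtp),
         scenarios = cfg$scenarios,
         psa = list(dirichlet_ess = cfg$psa$dirichlet_ess %||% 1000)),
    class = "hf_params")
  validate_parameter_set(params)
  params
}

#' Path to a bundled population configuration
#'
#' @param population `"hfref"` or `"hfpef"`.
#' @return path to the installed YAML file.
#' @export
hf_config_path <- function(population = c("hfref", "hfpef")) {
  population <- match.arg(population)
  system.file("extdata", paste0(population, ".yaml"), package = "hfcua",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hf_params <- function(x, ...) {
  cat(sprintf("<hf_params> %s cohort, start age %d, horizon %g y (%d cycles of %g mo)\n",
              x$population$label, x$population$start_age,
              x$cycle$horizon_years, x$cycle$n_cycles,
              x$cycle$cycle_length_months))
  cat(sprintf("  p_cv_death: control %.5f / empagliflozin %.5f per cycle\n",
              x$events$control$p_cv_death$value,
              x$events$empagliflozin$p_cv_death$value))
  cat(sprintf("  p_hosp:     control %.5f / empagliflozin %.5f; p_readmit %.3f\n",
              x$events$control$p_hosp$value,
              x$events$empagliflozin$p_hosp$value,
              x$events$p_readmit$value))
  invisible(x)
}
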