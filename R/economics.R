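#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost and QALYs (intervention minus comparator) at full
#' floating precision, the ICER where defined, dominance status, and the
#' willingness-to-pay classification against a pair of thresholds (1x and 3x
#' GDP per capita). Equality with a threshold resolves to the more favourable
#' class.
#'
#' @param intervention,comparator `arm_result` objects from [run_arm()].
#' @param thresholds numeric pair `c(lower, upper)` in USD/QALY.
#' @return an `incremental_result` list: `delta_cost`, `delta_qalys`, `icer`
#'   (`NA` when undefined), `dominance` (`"dominant"`, `"dominated"`,
#'   `"trade-off"`), `wtp_class`.
#' @export
compute_incremental <- function(intervention, comparator,
                                thresholds = c(12652.5, 37957.5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  dc <- intervention$total_discounted_cost - comparator$total_discounted_cost
  de <- intervention$total_discounted_qalys - comparator$total_discounted_qalys

  dominance <- if (dc <= 0 && de >= 0 && !(dc == 0 && de == 0)) {
    "dominant"
  } else if (dc >= 0 && de <= 0 && !(dc == 0 && de == 0)) {
    "dominated"
  } else {
    "trade-off"
  }

  icer <- if (de != 0 && dominance == "trade-off") dc / de else NA_real_

  wtp_class <- if (dominance == "dominant") {
    "very_cost_effective"
  } else if (dominance == "dominated") {
    "not_cost_effective"
  } else if (is.na(icer)) {
    NA_character_
  } else if (icer <= thresholds[1]) {
    "very_cost_effective"
  } else if (icer <= thresholds[2]) {
    "cost_effective"
  } else {
    "not_cost_effective"
  }

  structure(list(delta_cost = dc, delta_qalys = de, icer = icer,
                 dominance = dominance, wtp_class = wtp_class,
                 thresholds = thresholds),
            class = "incremental_result")
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qalys - delta_cost`; positive iff the intervention is
#' cost-effective at that willingness to pay.
#'
#' @param result an `incremental_result`, or a list/vector with `delta_cost`
#'   and `delta_qalys`.
#' @param wtp willingness to pay in USD/QALY (>= 0); may be a vector.
#' @return NMB in USD (vectorised over `wtp`).
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * result$delta_qalys - result$delta_cost
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("delta cost $%.2f, delta QALYs %.4f -> ICER %s (%s, %s)\n",
              x$delta_cost, x$delta_qalys,
              if (is.na(x$icer)) "undefined" else sprintf("$%.2f/QALY", x$icer),
              x$dominance, x$wtp_class))
  invisible(x)
}
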