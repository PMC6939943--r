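#' Incremental cost and effect
#'
#' @param intervention,comparator named vectors \code{c(cost=, qaly=)} on
#'   the per-patient scale.
#' @return \code{c(delta_cost=, delta_qaly=)} (intervention minus
#'   comparator).
#' @export
incremental <- function(intervention, comparator) {
  c(delta_cost = unname(intervention["cost"] - comparator["cost"]),
    delta_qaly = unname(intervention["qaly"] - comparator["qaly"]))
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' In the southwest quadrant (cheaper and less effective — the usual
#' position of bDMARD de-escalation) the ICER is reported as a positive
#' "savings per QALY lost"; in the northeast quadrant as the usual cost per
#' QALY gained. Dominant (cheaper, at least as effective) and dominated
#' (costlier, no more effective) comparisons get a label instead of a
#' number.
#'
#' @param delta_cost,delta_qaly incremental cost and QALYs.
#' @return list with \code{quadrant} (\code{"dominant"},
#'   \code{"dominated"}, \code{"NE"}, \code{"SW"} or \code{"indifferent"})
#'   and \code{icer} (numeric, \code{NA} when a label applies).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) {
    return(list(quadrant = "indifferent", icer = NA_real_))
  }
  if (delta_cost <= 0 && delta_qaly >= 0) {
    return(list(quadrant = "dominant", icer = NA_real_))
  }
  if (delta_cost >= 0 && delta_qaly <= 0) {
    return(list(quadrant = "dominated", icer = NA_real_))
  }
  q <- if (delta_cost < 0) "SW" else "NE"
  list(quadrant = q, icer = delta_cost / delta_qaly)
}

#' Net monetary benefit
#'
#' \eqn{\lambda \Delta QALY - \Delta cost}. For a de-escalation strategy in
#' the southwest quadrant, \eqn{\lambda} reads as the payer's required
#' savings per QALY lost; the intervention is cost-effective when the NMB is
#' positive.
#'
#' @param delta_cost,delta_qaly incremental cost and QALYs.
#' @param lambda willingness-to-pay (or required savings) threshold, EUR
#'   per QALY; vectorised.
#' @return NMB in EUR.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  lambda * delta_qaly - delta_cost
}

#' Base-case cost-utility analysis of all four strategies
#'
#' Runs the cohort model for standard care and the three de-escalation
#' strategies and compares each intervention against standard care.
#'
#' @param model a [deesc_model()] bundle.
#' @param decrement_scenario apply the bDMARD side-effect utility
#'   decrements?
#' @return a data.frame of class \code{cea_result}: one row per strategy
#'   with per-patient \code{cost} and \code{qaly}, and for interventions
#'   \code{delta_cost}, \code{delta_qaly}, \code{icer} and \code{quadrant}
#'   versus standard care.
#' @export
run_base_case <- function(model,
                          decrement_scenario = isTRUE(model$decrement_scenario)) {
  strategies <- c("standard", "tapering", "withdrawal", "taper_then_withdraw")
  tot <- vapply(strategies, function(s) {
    spec <- build_strategy(s, model$settings$cycle_months)
    run_strategy(spec, model$rows, model$mortality, model$econ,
                 model$settings, decrement_scenario)$totals
  }, c(cost = 0, qaly = 0))
  out <- data.frame(strategy = strategies, cost = tot["cost", ],
                    qaly = tot["qaly", ], delta_cost = NA_real_,
                    delta_qaly = NA_real_, icer = NA_real_,
                    quadrant = NA_character_, stringsAsFactors = FALSE)
  for (i in 2:4) {
    inc <- incremental(tot[, i], tot[, 1])
    ic <- icer(inc["delta_cost"], inc["delta_qaly"])
    out$delta_cost[i] <- inc["delta_cost"]
    out$delta_qaly[i] <- inc["delta_qaly"]
    out$icer[i] <- ic$icer
    out$quadrant[i] <- ic$quadrant
  }
  rownames(out) <- NULL
  class(out) <- c("cea_result", "data.frame")
  out
}

#' @export
print.cea_result <- function(x, ...) {
  y <- as.data.frame(x)
  y$cost <- round(y$cost); y$delta_cost <- round(y$delta_cost)
  y$qaly <- round(y$qaly, 4); y$delta_qaly <- round(y$delta_qaly, 4)
  y$icer <- round(y$icer)
  print(y)
  invisible(x)
}
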