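#' Switch a model into the bDMARD side-effect utility-decrement scenario
#'
#' Marks the model so that every subsequent run subtracts the full-dose
#' decrement from full-dose states and the half-dose decrement from tapered
#' states (withdrawn states keep the base utilities). Nothing else changes.
#'
#' @param model a [deesc_model()].
#' @return the modified model.
#' @export
apply_utility_decrement <- function(model) {
  model$decrement_scenario <- TRUE
  model
}

#' Strategy variant with patient-initiated bDMARD withdrawal
#'
#' Models imperfect persistence: patients who remain in remission-class
#' states for a given number of years withdraw the bDMARD on their own,
#' moving to the withdrawn-remission dynamics and costs. The clock is a
#' tunnel of state copies — under standard care it counts consecutive
#' full-dose remission cycles, under tapering consecutive tapered-remission
#' cycles. Relapse resumes the strategy's usual full-dose path (and restarts
#' every clock).
#'
#' @param strategy \code{"standard"} or \code{"tapering"}.
#' @param years years of stable remission before self-withdrawal; must be a
#'   whole number of cycles.
#' @param cycle_months cycle length (3 or 6).
#' @return a \code{strategy_spec}.
#' @export
build_self_withdrawal <- function(strategy = c("standard", "tapering"),
                                  years, cycle_months = 6) {
  make_strategy(match.arg(strategy), cycle_months,
                self_withdraw_years = years)
}

#' Strategy variant with one-time de-escalation eligibility
#'
#' Restricts de-escalation to a single attempt: relapse from a tapered or
#' withdrawn state routes into post-relapse copies of the full-dose states
#' that use standard-care dynamics and costs and have no path back to
#' de-escalation.
#'
#' @param strategy a de-escalation strategy name.
#' @param cycle_months cycle length (3 or 6).
#' @return a \code{strategy_spec}.
#' @export
build_one_time_deescalation <- function(strategy = c("tapering", "withdrawal",
                                                     "taper_then_withdraw"),
                                        cycle_months = 6) {
  make_strategy(match.arg(strategy), cycle_months, one_time = TRUE)
}

# run a named list of strategy specs (must include "standard") and return
# the incremental comparison of each intervention against standard care
run_comparison <- function(model, specs, settings = model$settings,
                           decrement_scenario = FALSE) {
  tot <- vapply(specs, function(spec) {
    run_strategy(spec, model$rows, model$mortality, model$econ, settings,
                 decrement_scenario)$totals
  }, c(cost = 0, qaly = 0))
  ints <- setdiff(names(specs), "standard")
  do.call(rbind, lapply(ints, function(s) {
    inc <- incremental(tot[, s], tot[, "standard"])
    ic <- icer(inc["delta_cost"], inc["delta_qaly"])
    data.frame(strategy = s, delta_cost = unname(inc["delta_cost"]),
               delta_qaly = unname(inc["delta_qaly"]), icer = ic$icer,
               quadrant = ic$quadrant, stringsAsFactors = FALSE)
  }))
}

#' Run the structural scenario suite
#'
#' Reruns the full comparison under each structural scenario: the bDMARD
#' side-effect utility decrement; self-withdrawal under standard care (and,
#' per the published design, under tapering) after 2, 3 or 5 years of
#' stable remission; one-time de-escalation eligibility; and horizons of
#' 5, 10, 20 and 40 years. The base case is included as the first column
#' for reference.
#'
#' @param model a [deesc_model()].
#' @param self_withdrawal_applies strategies whose machines the
#'   self-withdrawal scenario modifies; default both standard care and
#'   tapering. Restrict to \code{"standard"} to leave the tapering arm
#'   untouched.
#' @return a long data.frame: \code{scenario}, \code{strategy},
#'   \code{delta_cost}, \code{delta_qaly}, \code{icer}, \code{quadrant}.
#' @seealso [scenario_table()] for the wide layout.
#' @export
run_scenario_suite <- function(model,
                               self_withdrawal_applies = c("standard",
                                                           "tapering")) {
  cm <- model$settings$cycle_months
  base_specs <- lapply(stats::setNames(nm = c("standard", "tapering",
                                              "withdrawal",
                                              "taper_then_withdraw")),
                       build_strategy, cycle_months = cm)
  res <- list()
  keep <- function(scenario, df) {
    df$scenario <- scenario
    res[[length(res) + 1L]] <<- df[, c("scenario", "strategy", "delta_cost",
                                       "delta_qaly", "icer", "quadrant")]
  }
  keep("base", run_comparison(model, base_specs))
  keep("utility_decrement",
       run_comparison(model, base_specs, decrement_scenario = TRUE))
  for (y in c(2, 3, 5)) {
    specs <- base_specs
    if ("standard" %in% self_withdrawal_applies) {
      specs$standard <- build_self_withdrawal("standard", y, cm)
    }
    if ("tapering" %in% self_withdrawal_applies) {
      specs$tapering <- build_self_withdrawal("tapering", y, cm)
    }
    keep(paste0("self_withdrawal_", y, "y"), run_comparison(model, specs))
  }
  ot <- base_specs
  for (s in c("tapering", "withdrawal", "taper_then_withdraw")) {
    ot[[s]] <- build_one_time_deescalation(s, cm)
  }
  keep("one_time_deescalation", run_comparison(model, ot))
  for (h in c(5, 10, 20, 40)) {
    st <- model$settings
    settings <- run_settings(cycle_months = cm, horizon_years = h,
                             annual_discount_rate = st$annual_discount_rate,
                             half_cycle_correction = st$half_cycle_correction,
                             cohort_size = st$cohort_size)
    keep(paste0("horizon_", h, "y"),
         run_comparison(model, base_specs, settings = settings))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reshape scenario results into the published wide layout
#'
#' @param suite a [run_scenario_suite()] result.
#' @return a data.frame: one block of rows (delta cost, delta QALYs, ICER)
#'   per intervention, one column per scenario.
#' @export
scenario_table <- function(suite) {
  scen <- unique(suite$scenario)
  rows <- list()
  for (s in unique(suite$strategy)) {
    sub <- suite[suite$strategy == s, ]
    sub <- sub[match(scen, sub$scenario), ]
    icer_chr <- ifelse(is.na(sub$icer), sub$quadrant, round(sub$icer))
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = s, quantity = c("delta_cost", "delta_qaly", "icer"),
      rbind(round(sub$delta_cost), round(sub$delta_qaly, 4), icer_chr),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("strategy", "quantity", scen)
  rownames(out) <- NULL
  out
}

#' Write the scenario grid to CSV
#'
#' @param suite a [run_scenario_suite()] result.
#' @param path output CSV path.
#' @export
write_scenarios_csv <- function(suite, path) {
  utils::write.csv(scenario_table(suite), path, row.names = FALSE)
  invisible(path)
}
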