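#' Annual cost parameters
#'
#' Defaults are the 2017 German payer-perspective values: annual
#' pharmaceutical costs for the bDMARD, the csDMARD and concomitant
#' medication (NSAID + glucocorticoid), and annual other direct costs
#' (hospitalisation, rehabilitation, physician visits, surgery,
#' physiotherapy, imaging) by disease-activity class and age band.
#'
#' @param bdmard annual bDMARD cost at the full dose, EUR/year.
#' @param csdmard annual csDMARD cost, EUR/year.
#' @param concomitant annual concomitant medication cost, EUR/year.
#' @param other_le64 named vector \code{c(REM=, LDA=, MHDA=)} of annual other
#'   direct costs for patients aged 64 or less.
#' @param other_gt65 same for patients aged 65 or more.
#' @return an object of class \code{cost_set}.
#' @export
cost_set <- function(bdmard = 14834, csdmard = 1086, concomitant = 45,
                     other_le64 = c(REM = 1495, LDA = 2316, MHDA = 3713),
                     other_gt65 = c(REM = 2024, LDA = 2421, MHDA = 3881)) {
  stopifnot(bdmard >= 0, csdmard >= 0, concomitant >= 0,
            all(other_le64 >= 0), all(other_gt65 >= 0))
  structure(list(bdmard = bdmard, csdmard = csdmard, concomitant = concomitant,
                 other_le64 = other_le64[c("REM", "LDA", "MHDA")],
                 other_gt65 = other_gt65[c("REM", "LDA", "MHDA")]),
            class = "cost_set")
}

#' Utility parameters
#'
#' EQ-5D utilities by disease-activity class, plus the bDMARD side-effect
#' utility decrements used by the decrement scenario: the full-dose decrement
#' applies to all full-dose states, the half-dose decrement to tapered
#' states, and none to withdrawn states.
#'
#' @param REM,LDA,MHDA utilities by activity class (death is always 0).
#' @param decrement_full_dose,decrement_half_dose scenario decrements.
#' @return an object of class \code{utility_set}.
#' @export
utility_set <- function(REM = 0.75, LDA = 0.71, MHDA = 0.60,
                        decrement_full_dose = 0.0567,
                        decrement_half_dose = 0.0284) {
  u <- c(REM = REM, LDA = LDA, MHDA = MHDA)
  stopifnot(all(u >= 0 & u <= 1), decrement_full_dose >= 0,
            decrement_half_dose >= 0,
            decrement_half_dose <= decrement_full_dose)
  structure(list(utility = u, decrement_full_dose = decrement_full_dose,
                 decrement_half_dose = decrement_half_dose),
            class = "utility_set")
}

#' Annual total direct cost of a health state
#'
#' Other direct costs by activity class and age band, plus csDMARD and
#' concomitant medication, plus the bDMARD cost scaled by the state's dose
#' fraction (1 full, 0.5 tapered, 0 withdrawn). The age band switches when
#' the attained age reaches 65. Death costs nothing.
#'
#' @param activity \code{"REM"}, \code{"LDA"}, \code{"MHDA"} or
#'   \code{"DEAD"} (vectorised).
#' @param dose \code{"full"}, \code{"half"} or \code{"zero"} (vectorised).
#' @param age attained age in years.
#' @param costs a [cost_set()].
#' @return annual cost in EUR/year.
#' @export
state_annual_cost <- function(activity, dose, age, costs = cost_set()) {
  n <- max(length(activity), length(dose))
  activity <- rep_len(activity, n); dose <- rep_len(dose, n)
  dose_frac <- c(full = 1, half = 0.5, zero = 0)[dose]
  other <- if (age >= 65) costs$other_gt65 else costs$other_le64
  out <- other[activity] + costs$csdmard + costs$concomitant +
    costs$bdmard * dose_frac
  out[activity == "DEAD"] <- 0
  unname(out)
}

#' Utility of a health state
#'
#' Base-case utility depends only on the activity class (all REM-class
#' states share one value, and so on). Under the decrement scenario the
#' full-dose decrement is subtracted in full-dose states and the half-dose
#' decrement in tapered states, floored at zero.
#'
#' @param activity,dose as in [state_annual_cost()] (vectorised).
#' @param utilities a [utility_set()].
#' @param decrement_scenario apply the bDMARD side-effect decrements?
#' @return utility weights in \[0, 1\].
#' @export
state_utility <- function(activity, dose, utilities = utility_set(),
                          decrement_scenario = FALSE) {
  n <- max(length(activity), length(dose))
  activity <- rep_len(activity, n); dose <- rep_len(dose, n)
  u <- ifelse(activity == "DEAD", 0, utilities$utility[activity])
  if (decrement_scenario) {
    dec <- c(full = utilities$decrement_full_dose,
             half = utilities$decrement_half_dose, zero = 0)[dose]
    u <- pmax(0, u - ifelse(activity == "DEAD", 0, dec))
  }
  unname(u)
}

#' Read the full economic parameter configuration
#'
#' Loads a YAML file mirroring the published parameter table: base-case
#' costs and utilities, deterministic sensitivity bounds, probabilistic
#' sampling distributions (gamma for costs, Dirichlet concentrations for
#' transition rows, beta for utilities), mortality settings and run
#' settings. See the packaged \code{table2_params.yaml} for the schema.
#'
#' @param path YAML path; defaults to the packaged parameter set.
#' @return a list of class \code{econ_params} with elements \code{costs}
#'   ([cost_set()]), \code{utilities} ([utility_set()]), \code{dsa},
#'   \code{psa}, \code{mortality} and \code{settings}.
#' @export
read_econ_params <- function(path = system.file("extdata", "table2_params.yaml",
                                                package = "deescra")) {
  raw <- yaml::read_yaml(path)
  build_econ_params(raw)
}

# assemble the econ_params object from the parsed YAML structure
build_econ_params <- function(raw) {
  cs <- raw$costs
  costs <- cost_set(
    bdmard = cs$bdmard$base, csdmard = cs$csdmard$base,
    concomitant = cs$concomitant$base,
    other_le64 = unlist(lapply(cs$other_direct$le64, `[[`, "base")),
    other_gt65 = unlist(lapply(cs$other_direct$gt65, `[[`, "base")))
  ut <- raw$utilities
  utilities <- utility_set(
    REM = ut$REM$base, LDA = ut$LDA$base, MHDA = ut$MHDA$base,
    decrement_full_dose = ut$decrement_full_dose,
    decrement_half_dose = ut$decrement_half_dose)
  out <- list(costs = costs, utilities = utilities, raw = raw,
              mortality = raw$mortality, settings = raw$settings)
  class(out) <- "econ_params"
  out
}

#' Default economic parameters (published base case)
#'
#' @return the packaged parameter set as an \code{econ_params} object,
#'   constructed in code (identical to reading the shipped YAML fixture).
#' @export
default_econ_params <- function() {
  build_econ_params(table2_params())
}
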