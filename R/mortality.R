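#' Read a sex-specific annual life table
#'
#' Expects columns \code{age}, \code{q_female}, \code{q_male}: the annual
#' probability of death at each (integer) age for each sex. A national
#' all-cause table in this layout can be substituted for the packaged
#' synthetic fixture.
#'
#' @param path CSV path.
#' @return a validated \code{life_table} data.frame.
#' @seealso [make_life_table()]
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df)
}

#' @rdname read_life_table
#' @param df a data.frame to validate.
#' @export
validate_life_table <- function(df) {
  req <- c("age", "q_female", "q_male")
  if (!all(req %in% names(df))) {
    stop("life table needs columns: ", paste(req, collapse = ", "))
  }
  if (is.unsorted(df$age, strictly = TRUE)) stop("life table ages must be strictly increasing")
  if (any(df$q_female < 0 | df$q_female > 1 | df$q_male < 0 | df$q_male > 1)) {
    stop("death probabilities must lie in [0, 1]")
  }
  class(df) <- c("life_table", "data.frame")
  df
}

#' Cohort mortality model
#'
#' Bundles a life table with the cohort's sex mix, starting age and the
#' standardised mortality ratio (SMR) applied to patients in medium-to-high
#' disease activity. The default 3:1 female:male mix reflects the sex
#' distribution of RA patients; the default SMR of 2.34 reflects the excess
#' mortality observed for moderate/severe RA relative to the general
#' population.
#'
#' @param life_table a \code{life_table} (see [read_life_table()]).
#' @param female_share proportion of females in the cohort.
#' @param smr_mhda mortality multiplier for the M/HDA severity class (>= 1).
#' @param start_age cohort age in years at model start.
#' @return an object of class \code{mortality_model}.
#' @export
mortality_model <- function(life_table, female_share = 0.75, smr_mhda = 2.34,
                            start_age = 45) {
  life_table <- validate_life_table(as.data.frame(life_table))
  if (female_share < 0 || female_share > 1) stop("female_share must lie in [0, 1]")
  if (smr_mhda < 1) stop("smr_mhda must be >= 1")
  structure(list(life_table = life_table, female_share = female_share,
                 smr_mhda = smr_mhda, start_age = start_age),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("mortality model: start age %s, female share %.2f, M/HDA SMR %.2f, life table ages %d-%d\n",
              x$start_age, x$female_share, x$smr_mhda,
              min(x$life_table$age), max(x$life_table$age)))
  invisible(x)
}

#' Per-cycle death probability at a given model cycle
#'
#' The attained age is \code{start_age + cycle_index * cycle_months / 12},
#' floored to an integer to index the annual table. The sex-weighted annual
#' probability is converted to the cycle length by compound survival,
#' \eqn{q_c = 1 - (1 - q_a)^{m/12}}, and multiplied by the SMR (capped at 1)
#' for the M/HDA severity class.
#'
#' @param model a \code{mortality_model}.
#' @param cycle_index zero-based cycle index (vectorised).
#' @param severity_class \code{"rem_lda"} or \code{"mhda"}.
#' @param cycle_months cycle length in months.
#' @return per-cycle death probabilities.
#' @export
cycle_death_probability <- function(model, cycle_index,
                                    severity_class = c("rem_lda", "mhda"),
                                    cycle_months = 6) {
  severity_class <- match.arg(severity_class)
  age <- floor(model$start_age + cycle_index * cycle_months / 12)
  idx <- match(age, model$life_table$age)
  if (anyNA(idx)) {
    stop("attained age ", paste(unique(age[is.na(idx)]), collapse = ", "),
         " outside life-table coverage")
  }
  q_annual <- model$female_share * model$life_table$q_female[idx] +
    (1 - model$female_share) * model$life_table$q_male[idx]
  q <- 1 - (1 - q_annual)^(cycle_months / 12)
  if (severity_class == "mhda") q <- pmin(1, q * model$smr_mhda)
  q
}

# cycles x {rem_lda, mhda} matrix of per-cycle death probabilities
death_prob_table <- function(model, n_cycles, cycle_months) {
  k <- seq_len(n_cycles) - 1L
  cbind(rem_lda = cycle_death_probability(model, k, "rem_lda", cycle_months),
        mhda = cycle_death_probability(model, k, "mhda", cycle_months))
}
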