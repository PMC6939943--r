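# shared fixtures, built once per test run
arms_tbl <- table1_studies()
base_model <- deesc_model()
base_case <- run_base_case(base_model)

# independent step-by-step evaluation of the DerSimonian-Laird estimator,
# written against the formulas rather than the package code path
dl_oracle <- function(p, n) {
  v <- p * (1 - p) / n
  p <- p[v > 0]; n <- n[v > 0]; v <- v[v > 0]
  if (length(p) == 0) return(0)
  if (length(p) == 1) return(p)
  w <- 1 / v
  mu_fe <- sum(w * p) / sum(w)
  Q <- sum(w * (p - mu_fe)^2)
  tau2 <- max(0, (Q - (length(p) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  sum(ws * p) / sum(ws)
}

# toy life table with constant annual mortality (or zero)
flat_life_table <- function(q = 0, ages = 40:110) {
  validate_life_table(data.frame(age = ages, q_female = q, q_male = q))
}

zero_mortality <- function(start_age = 45) {
  mortality_model(flat_life_table(0), smr_mhda = 2.34, start_age = start_age)
}

# minimal single-alive-state strategy for engine-level checks
single_state_spec <- function(cycle_months = 6, activity = "REM",
                              dose = "full") {
  states <- data.frame(name = "ONLY", activity = activity, dose = dose,
                       tag = "plain", row_key = "standard.REM",
                       dest_REM = "ONLY", dest_LDA = "ONLY",
                       dest_MHDA = "ONLY", stringsAsFactors = FALSE)
  structure(list(name = "toy", cycle_months = cycle_months, one_time = FALSE,
                 self_withdraw_years = NULL, states = states,
                 start_state = "ONLY"), class = "strategy_spec")
}

single_state_rows <- list("standard.REM" = c(REM = 1, LDA = 0, MHDA = 0))
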