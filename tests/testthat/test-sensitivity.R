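test_that("the DSA parameter list covers costs, utilities, transitions, discount and horizon", {
  pars <- dsa_parameters(base_model)
  expect_equal(nrow(pars), 9 + 3 + 21 + 2)
  expect_true(all(pars$low <= pars$high))
  bd <- pars[pars$name == "cost_bdmard", ]
  expect_equal(c(bd$low, bd$high), c(8147, 21520))
  expect_equal(pars[pars$name == "discount_rate", c("low", "high")],
               data.frame(low = 0, high = 0.06),
               ignore_attr = TRUE)
})

test_that("setting a parameter to its base value reproduces the base case exactly", {
  m1 <- apply_dsa_value(base_model, "cost", "bdmard", 14834)
  expect_identical(run_base_case(m1), base_case)
  m2 <- apply_dsa_value(base_model, "utility", "REM", 0.75)
  expect_identical(run_base_case(m2), base_case)
  m3 <- apply_dsa_value(base_model, "discount", "",
                        base_model$settings$annual_discount_rate)
  expect_identical(run_base_case(m3), base_case)
})

test_that("transition-cell perturbations keep rows stochastic", {
  m <- apply_dsa_value(base_model, "transition", "tapering.REM|MHDA", 0.1458)
  row <- m$rows[["tapering.REM"]]
  expect_equal(sum(row), 1, tolerance = 1e-12)
  # the perturbed cell keeps its share after proportional renormalisation
  df <- m$rows_df
  sel <- df$regimen == "tapering" & df$from_state == "REM"
  p <- stats::setNames(df$pooled_p[sel], df$to_state[sel])
  p["MHDA"] <- 0.1458
  expect_equal(unname(row["MHDA"]), unname(p["MHDA"] / sum(p)))
})

test_that("tornado reruns bracket the base case for monotone parameters", {
  pars <- dsa_parameters(base_model)
  sub <- pars[pars$name %in% c("cost_bdmard", "utility_MHDA",
                               "discount_rate"), ]
  tor <- run_dsa(base_model, sub)
  expect_equal(nrow(tor), 3 * 2 * 3)
  base_dc <- base_case$delta_cost[base_case$strategy == "tapering"]
  for (p in unique(tor$parameter)) {
    dc <- tor$delta_cost[tor$parameter == p & tor$strategy == "tapering"]
    if (p == "cost_bdmard") {
      expect_true(min(dc) <= base_dc && base_dc <= max(dc))
    }
  }
  # cheaper bDMARDs shrink the savings, costlier ones grow them
  dc <- tor[tor$parameter == "cost_bdmard" & tor$strategy == "withdrawal", ]
  expect_gt(abs(dc$delta_cost[dc$bound == "high"]),
            abs(dc$delta_cost[dc$bound == "low"]))
  # heavier discounting shrinks the (late-accruing) savings
  disc <- tor[tor$parameter == "discount_rate" & tor$strategy == "tapering", ]
  expect_lt(abs(disc$delta_cost[disc$bound == "high"]),
            abs(disc$delta_cost[disc$bound == "low"]))
  # results arrive sorted by the incremental-cost swing
  expect_true(!is.unsorted(rev(tor$range_delta_cost)))
})

test_that("the horizon bounds rerun the model structurally", {
  pars <- dsa_parameters(base_model)
  h <- pars[pars$name == "horizon_cycles", ]
  tor <- run_dsa(base_model, h)
  short <- tor[tor$bound == "low" & tor$strategy == "tapering", ]
  long <- tor[tor$bound == "high" & tor$strategy == "tapering", ]
  expect_lt(abs(short$delta_cost), abs(long$delta_cost))
})

test_that("sampled parameters follow the published distributions", {
  raw <- base_model$econ$raw
  # gamma parameterisation: shape (mean/sd)^2, scale sd^2/mean
  set.seed(99)
  g <- stats::rgamma(1e5, shape = (14834 / 6687)^2, scale = 6687^2 / 14834)
  expect_equal(mean(g), 14834, tolerance = 0.01)
  expect_equal(stats::sd(g), 6687, tolerance = 0.02)
  # beta means match the base utilities analytically
  for (a in c("REM", "LDA", "MHDA")) {
    p <- raw$utilities[[a]]$psa
    expect_equal(p$alpha / (p$alpha + p$beta), raw$utilities[[a]]$base,
                 tolerance = 1e-3)
  }
  set.seed(123)
  draws <- replicate(400, sample_parameters(base_model), simplify = FALSE)
  for (d in draws[1:20]) {
    for (r in d$rows) expect_equal(sum(r), 1, tolerance = 1e-12)
    expect_true(all(d$utilities >= 0 & d$utilities <= 1))
    expect_true(d$costs$bdmard > 0)
  }
  bd <- vapply(draws, function(d) d$costs$bdmard, numeric(1))
  expect_equal(mean(bd), 14834, tolerance = 0.06)
  # Dirichlet rows centre on the concentration shares
  rem <- t(vapply(draws, function(d) d$rows[["standard.REM"]], numeric(3)))
  expect_equal(colMeans(rem), c(111, 8, 6) / 125, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("degenerate sampling reproduces the base case draw by draw", {
  psa <- run_psa(base_model, n_iter = 3, seed = 1, degenerate = TRUE)
  for (s in psa$interventions) {
    expect_equal(psa$draws[[paste0("delta_cost_", s)]],
                 rep(base_case$delta_cost[base_case$strategy == s], 3),
                 tolerance = 1e-9)
    expect_equal(psa$draws[[paste0("delta_qaly_", s)]],
                 rep(base_case$delta_qaly[base_case$strategy == s], 3),
                 tolerance = 1e-9)
  }
})

test_that("seeded PSA runs are bit-reproducible and quadrant shares partition", {
  p1 <- run_psa(base_model, n_iter = 60, seed = 7, keep_parameters = TRUE)
  p2 <- run_psa(base_model, n_iter = 60, seed = 7, keep_parameters = TRUE)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(base_model, n_iter = 60, seed = 8)
  expect_false(identical(p1$draws$delta_cost_tapering,
                         p3$draws$delta_cost_tapering))
  sh <- quadrant_shares(p1)
  expect_equal(unname(rowSums(sh)), rep(1, 3))
  expect_true(all(sh >= 0 & sh <= 1))
})

test_that("the acceptability curve reduces to quadrant shares at the extremes", {
  fake <- structure(list(
    draws = data.frame(
      iteration = 1:6,
      delta_cost_tapering = c(-10, -20, -5, 4, -8, 2),
      delta_qaly_tapering = c(-0.1, 0.2, -0.05, -0.2, 0.1, 0.3),
      delta_cost_withdrawal = c(-10, -20, -5, -4, -8, -2),
      delta_qaly_withdrawal = c(-0.1, -0.2, -0.05, -0.2, -0.1, -0.3),
      delta_cost_taper_then_withdraw = rep(-1, 6),
      delta_qaly_taper_then_withdraw = rep(-0.01, 6)),
    n_iter = 6, seed = 1,
    interventions = c("tapering", "withdrawal", "taper_then_withdraw")),
    class = "psa_result")
  cc <- ceac(fake, lambda = c(0, 50, 1e9))
  d <- fake$draws
  expect_equal(cc$tapering[1], mean(d$delta_cost_tapering < 0))
  # at huge lambda the sign of the QALY delta decides
  expect_equal(cc$tapering[3], mean(d$delta_qaly_tapering > 0))
  # all-SW interventions give monotone non-increasing curves
  cc_sw <- ceac(fake, lambda = seq(0, 2000, by = 100))
  expect_true(all(diff(cc_sw$withdrawal) <= 0))
  expect_true(all(diff(cc_sw$taper_then_withdraw) <= 0))
})

test_that("PSA and CEAC tables export as CSV", {
  psa <- run_psa(base_model, n_iter = 20, seed = 5, keep_parameters = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(psa, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 20)
  expect_true("cost_bdmard" %in% names(back))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(ceac(psa, lambda = c(0, 1e4)), path2)
  expect_equal(nrow(utils::read.csv(path2)), 2)
})
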