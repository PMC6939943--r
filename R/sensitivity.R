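#' Deterministic sensitivity parameters
#'
#' Enumerates every one-way parameter with its bounds: the nine annual cost
#' parameters (varied by 45 percent in the published analysis), the three
#' utilities (95 percent confidence bounds), the 21 pooled transition cells
#' (pooling confidence bounds), the annual discount rate (0 to 6 percent)
#' and the model horizon (a structural rerun at the bound cycle counts).
#'
#' @param model a [deesc_model()].
#' @return a data.frame with \code{name}, \code{type}, \code{target},
#'   \code{low}, \code{high}.
#' @export
dsa_parameters <- function(model) {
  raw <- model$econ$raw
  out <- list()
  add <- function(name, type, target, low, high) {
    out[[length(out) + 1L]] <<- data.frame(
      name = name, type = type, target = target, low = low, high = high,
      stringsAsFactors = FALSE)
  }
  for (nm in c("bdmard", "csdmard", "concomitant")) {
    add(paste0("cost_", nm), "cost", nm, raw$costs[[nm]]$dsa_low,
        raw$costs[[nm]]$dsa_high)
  }
  for (band in c("le64", "gt65")) {
    for (act in c("REM", "LDA", "MHDA")) {
      p <- raw$costs$other_direct[[band]][[act]]
      add(paste0("cost_other_", band, "_", act), "cost",
          paste(band, act, sep = "."), p$dsa_low, p$dsa_high)
    }
  }
  for (act in c("REM", "LDA", "MHDA")) {
    p <- raw$utilities[[act]]
    add(paste0("utility_", act), "utility", act, p$dsa_low, p$dsa_high)
  }
  for (key in names(raw$transitions)) {
    cells <- raw$transitions[[key]]$cells
    for (to in names(cells)) {
      add(paste0("tp_", key, "_", to), "transition",
          paste(key, to, sep = "|"), cells[[to]]$dsa_low,
          cells[[to]]$dsa_high)
    }
  }
  s <- model$econ$settings
  add("discount_rate", "discount", "", s$discount_dsa[1], s$discount_dsa[2])
  add("horizon_cycles", "horizon", "", s$horizon_dsa_cycles[1],
      s$horizon_dsa_cycles[2])
  do.call(rbind, out)
}

# return a copy of the model with one parameter set to `value`
apply_dsa_value <- function(model, type, target, value) {
  if (type == "cost") {
    cs <- model$econ$costs
    if (target %in% c("bdmard", "csdmard", "concomitant")) {
      cs[[target]] <- value
    } else {
      parts <- strsplit(target, ".", fixed = TRUE)[[1]]
      slot <- if (parts[1] == "le64") "other_le64" else "other_gt65"
      cs[[slot]][parts[2]] <- value
    }
    model$econ$costs <- cs
  } else if (type == "utility") {
    model$econ$utilities$utility[target] <- value
  } else if (type == "transition") {
    parts <- strsplit(target, "|", fixed = TRUE)[[1]]
    key <- parts[1]; to <- parts[2]
    kp <- strsplit(key, ".", fixed = TRUE)[[1]]
    df <- model$rows_df
    sel <- df$regimen == kp[1] & df$from_state == kp[2]
    p <- stats::setNames(df$pooled_p[sel], df$to_state[sel])
    p[to] <- value
    if (sum(p) <= 0) return(NULL)
    df$normalized_p[sel] <- (p / sum(p))[df$to_state[sel]]
    model$rows_df <- df
    model$rows <- transition_row_list(df)
  } else if (type == "discount") {
    model$settings$annual_discount_rate <- value
  } else if (type == "horizon") {
    s <- model$settings
    model$settings <- run_settings(
      cycle_months = s$cycle_months,
      horizon_years = value * s$cycle_months / 12,
      annual_discount_rate = s$annual_discount_rate,
      half_cycle_correction = s$half_cycle_correction,
      cohort_size = s$cohort_size)
  } else stop("unknown DSA parameter type: ", type)
  model
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full model with each parameter at its lower and upper bound,
#' everything else at base. When a transition cell is varied, the other
#' cells of its row are rescaled proportionally so the row remains
#' stochastic. Results are sorted by the width of the incremental-cost
#' swing (the tornado ordering).
#'
#' @param model a [deesc_model()].
#' @param parameters a [dsa_parameters()] data.frame (or a subset).
#' @return a data.frame with one row per parameter, bound and intervention:
#'   \code{delta_cost}, \code{delta_qaly}, \code{icer}, plus a
#'   \code{range_delta_cost} column carrying each parameter's swing.
#' @export
run_dsa <- function(model, parameters = dsa_parameters(model)) {
  base <- run_base_case(model)
  res <- list()
  for (i in seq_len(nrow(parameters))) {
    par <- parameters[i, ]
    for (bound in c("low", "high")) {
      value <- par[[bound]]
      mod <- apply_dsa_value(model, par$type, par$target, value)
      if (is.null(mod)) {
        warning("bound produces an invalid probability row for ", par$name,
                "; skipped")
        next
      }
      cc <- run_base_case(mod)
      res[[length(res) + 1L]] <- data.frame(
        parameter = par$name, bound = bound, bound_value = value,
        strategy = cc$strategy[-1], delta_cost = cc$delta_cost[-1],
        delta_qaly = cc$delta_qaly[-1], icer = cc$icer[-1],
        quadrant = cc$quadrant[-1], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  swing <- vapply(split(out$delta_cost, out$parameter),
                  function(x) diff(range(x)), numeric(1))
  out$range_delta_cost <- swing[out$parameter]
  out <- out[order(-out$range_delta_cost, out$parameter, out$bound,
                   out$strategy), ]
  rownames(out) <- NULL
  attr(out, "base") <- base
  out
}

#' Draw one probabilistic parameter set
#'
#' Samples every uncertain parameter from its published distribution:
#' annual costs from gamma distributions parameterised by
#' \eqn{shape = (mean/sd)^2}, \eqn{scale = sd^2/mean}; each transition row
#' from a Dirichlet distribution with the published concentration vector
#' (used directly as the row); utilities from beta distributions with the
#' published shapes. Parameters are sampled independently. Uses the current
#' RNG state — seed control belongs to the caller (see [run_psa()]).
#'
#' @param model a [deesc_model()].
#' @param degenerate if \code{TRUE}, return the base-case values unchanged
#'   (every distribution collapsed to its base; diagnostic use).
#' @return a list with \code{costs} ([cost_set()]), \code{utilities}
#'   (named vector), \code{rows} (named list of rows summing to 1) and
#'   \code{flat} (a named numeric vector of everything sampled).
#' @export
sample_parameters <- function(model, degenerate = FALSE) {
  raw <- model$econ$raw
  if (degenerate) {
    u <- model$econ$utilities$utility
    rows <- model$rows
  } else {
    rgam <- function(p) stats::rgamma(1, shape = (p$psa$mean / p$psa$sd)^2,
                                      scale = p$psa$sd^2 / p$psa$mean)
    bd <- rgam(raw$costs$bdmard); cd <- rgam(raw$costs$csdmard)
    cc <- rgam(raw$costs$concomitant)
    o64 <- vapply(raw$costs$other_direct$le64, rgam, numeric(1))
    o65 <- vapply(raw$costs$other_direct$gt65, rgam, numeric(1))
    u <- vapply(c("REM", "LDA", "MHDA"), function(a) {
      p <- raw$utilities[[a]]$psa
      stats::rbeta(1, p$alpha, p$beta)
    }, numeric(1))
    rows <- lapply(raw$transitions, function(tr) {
      g <- stats::rgamma(3, shape = tr$dirichlet, scale = 1)
      stats::setNames(g / sum(g), c("REM", "LDA", "MHDA"))
    })
  }
  if (!degenerate) {
    costs <- cost_set(bdmard = bd, csdmard = cd, concomitant = cc,
                      other_le64 = o64, other_gt65 = o65)
  } else {
    costs <- model$econ$costs
  }
  flat <- c(cost_bdmard = costs$bdmard, cost_csdmard = costs$csdmard,
            cost_concomitant = costs$concomitant,
            stats::setNames(costs$other_le64, paste0("cost_le64_", names(costs$other_le64))),
            stats::setNames(costs$other_gt65, paste0("cost_gt65_", names(costs$other_gt65))),
            stats::setNames(u, paste0("utility_", names(u))),
            stats::setNames(unlist(rows), paste0("tp_", rep(names(rows), each = 3), "_",
                                                 rep(c("REM", "LDA", "MHDA"), length(rows)))))
  list(costs = costs, utilities = u, rows = rows, flat = flat)
}

# precompute everything about a strategy that does not change across PSA
# draws: destination indices, row-key indices, death probabilities, state
# metadata, discount factors and age bands
strategy_precompute <- function(spec, model) {
  st <- spec$states
  ns <- nrow(st)
  settings <- model$settings
  row_keys <- names(model$rows)
  dest_idx <- cbind(match(st$dest_REM, st$name), match(st$dest_LDA, st$name),
                    match(st$dest_MHDA, st$name))
  n <- settings$n_cycles
  cyc_years <- settings$cycle_months / 12
  list(spec = spec, ns = ns,
       row_idx = match(st$row_key, row_keys), dest_idx = dest_idx,
       cls = ifelse(st$activity == "MHDA", 2L, 1L),
       act = st$activity,
       dose_frac = c(full = 1, half = 0.5, zero = 0)[st$dose],
       start = match(spec$start_state, st$name),
       pd = death_prob_table(model$mortality, n, settings$cycle_months),
       disc = (1 + settings$annual_discount_rate)^(-(seq_len(n) * cyc_years)),
       hi_band = (model$mortality$start_age + (seq_len(n) - 1) * cyc_years) >= 65,
       cyc_years = cyc_years, n = n, cohort = settings$cohort_size,
       hcc = settings$half_cycle_correction)
}

# per-patient discounted totals for one strategy under one parameter set;
# P is a (#row-keys x 3) matrix of row probabilities
totals_fast <- function(pre, P, costs, u) {
  ns <- pre$ns
  D <- matrix(0, ns, ns)
  for (j in 1:3) {
    idx <- cbind(seq_len(ns), pre$dest_idx[, j])
    D[idx] <- D[idx] + P[pre$row_idx, j]
  }
  occ <- trace_engine(D, pre$pd, pre$cls, pre$start, pre$n, pre$cohort)
  avg <- if (pre$hcc) (occ[seq_len(pre$n), ] + occ[seq_len(pre$n) + 1, ]) / 2
         else occ[seq_len(pre$n), , drop = FALSE]
  cost_lo <- c(costs$other_le64[pre$act] + costs$csdmard + costs$concomitant +
                 costs$bdmard * pre$dose_frac, 0)
  cost_hi <- c(costs$other_gt65[pre$act] + costs$csdmard + costs$concomitant +
                 costs$bdmard * pre$dose_frac, 0)
  uvec <- c(u[pre$act], 0)
  cost <- as.numeric(avg %*% cost_lo)
  cost[pre$hi_band] <- as.numeric(avg %*% cost_hi)[pre$hi_band]
  qaly <- as.numeric(avg %*% uvec)
  c(cost = sum(cost * pre$disc) * pre$cyc_years / pre$cohort,
    qaly = sum(qaly * pre$disc) * pre$cyc_years / pre$cohort)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: each iteration draws one parameter set
#' ([sample_parameters()]), runs all four strategies on it, and records the
#' incremental cost and QALYs of each intervention against standard care
#' together with its cost-effectiveness-plane quadrant. Fully reproducible
#' under a seed.
#'
#' @param model a [deesc_model()].
#' @param n_iter number of iterations.
#' @param seed RNG seed (all randomness flows from it).
#' @param degenerate collapse all distributions to their base values
#'   (diagnostic: every draw then reproduces the base case).
#' @param keep_parameters keep the flattened sampled parameters as columns
#'   of the draw table?
#' @return an object of class \code{psa_result}: the draw table plus
#'   metadata (\code{n_iter}, \code{seed}).
#' @export
run_psa <- function(model, n_iter = 10000, seed = 42, degenerate = FALSE,
                    keep_parameters = FALSE) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  set.seed(seed)
  strategies <- c("standard", "tapering", "withdrawal", "taper_then_withdraw")
  pres <- lapply(strategies, function(s) {
    strategy_precompute(build_strategy(s, model$settings$cycle_months), model)
  })
  names(pres) <- strategies
  row_keys <- names(model$rows)
  draws <- vector("list", n_iter)
  par_rows <- if (keep_parameters) vector("list", n_iter) else NULL
  for (it in seq_len(n_iter)) {
    ps <- sample_parameters(model, degenerate)
    P <- do.call(rbind, ps$rows[row_keys])
    tot <- vapply(pres, totals_fast, c(cost = 0, qaly = 0), P = P,
                  costs = ps$costs, u = ps$utilities)
    dc <- tot["cost", -1] - tot["cost", 1]
    dq <- tot["qaly", -1] - tot["qaly", 1]
    draws[[it]] <- c(dc, dq)
    if (keep_parameters) par_rows[[it]] <- ps$flat
  }
  m <- do.call(rbind, draws)
  out <- data.frame(iteration = seq_len(n_iter),
                    delta_cost_tapering = m[, 1],
                    delta_cost_withdrawal = m[, 2],
                    delta_cost_taper_then_withdraw = m[, 3],
                    delta_qaly_tapering = m[, 4],
                    delta_qaly_withdrawal = m[, 5],
                    delta_qaly_taper_then_withdraw = m[, 6])
  if (keep_parameters) out <- cbind(out, do.call(rbind, par_rows))
  structure(list(draws = out, n_iter = n_iter, seed = seed,
                 interventions = strategies[-1]), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s)\n", x$n_iter, x$seed))
  print(round(quadrant_shares(x), 4))
  invisible(x)
}

#' Cost-effectiveness-plane quadrant shares of a PSA
#'
#' @param psa a [run_psa()] result.
#' @return a matrix: interventions x quadrants
#'   (\code{dominant}, \code{SW}, \code{NE}, \code{dominated}), each row
#'   summing to 1.
#' @export
quadrant_shares <- function(psa) {
  d <- psa$draws
  t(vapply(psa$interventions, function(s) {
    dc <- d[[paste0("delta_cost_", s)]]
    dq <- d[[paste0("delta_qaly_", s)]]
    dominant <- dc <= 0 & dq >= 0 & !(dc == 0 & dq == 0)
    sw <- dc < 0 & dq < 0
    ne <- dc > 0 & dq > 0
    c(dominant = mean(dominant), SW = mean(sw), NE = mean(ne),
      dominated = mean(!dominant & !sw & !ne))
  }, numeric(4)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay (or required-savings) threshold, the share
#' of PSA draws with positive net monetary benefit. Dominant draws count at
#' every threshold, dominated draws never.
#'
#' @param psa a [run_psa()] result.
#' @param lambda numeric grid of thresholds (EUR per QALY).
#' @return a data.frame of class \code{ceac_curve}: \code{lambda} and one
#'   probability column per intervention.
#' @export
ceac <- function(psa, lambda = seq(0, 500000, by = 10000)) {
  d <- psa$draws
  out <- data.frame(lambda = lambda)
  for (s in psa$interventions) {
    dc <- d[[paste0("delta_cost_", s)]]
    dq <- d[[paste0("delta_qaly_", s)]]
    out[[s]] <- vapply(lambda, function(l) {
      mean(net_monetary_benefit(dc, dq, l) > 0)
    }, numeric(1))
  }
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Write PSA draws / CEAC / tornado tables to CSV
#'
#' @param x a \code{psa_result}, \code{ceac_curve} or [run_dsa()] table.
#' @param path output CSV path.
#' @export
write_sensitivity_csv <- function(x, path) {
  df <- if (inherits(x, "psa_result")) x$draws else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
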