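#' Read an arm-level study pool from CSV
#'
#' The study pool holds one row per trial arm: how many patients ended a
#' follow-up period in remission (REM), low disease activity (LDA) or medium
#' to high disease activity (M/HDA), together with the arm's baseline disease
#' activity and the treatment regimen (standard full-dose care, tapering to a
#' half dose, or complete withdrawal of the bDMARD).
#'
#' Required columns: \code{study_id, year, substance, group, design,
#' baseline_state, regimen, n, count_rem, count_lda, count_mhda,
#' followup_months}. Optional columns \code{trans_rem, trans_lda, trans_mhda}
#' carry per-cycle transition probabilities as published (used by the
#' \code{"strict"} pooling mode), with \code{trans_source} flagging their
#' provenance.
#'
#' @param path path to a CSV file in the documented layout.
#' @return a validated \code{data.frame} of class \code{study_pool}.
#' @seealso [build_transition_rows()], [table1_studies()]
#' @export
read_study_pool <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_pool(df)
}

#' @rdname read_study_pool
#' @param arms a data.frame to validate in place of a file.
#' @export
validate_study_pool <- function(arms) {
  req <- c("study_id", "year", "substance", "group", "design",
           "baseline_state", "regimen", "n", "count_rem", "count_lda",
           "count_mhda", "followup_months")
  miss <- setdiff(req, names(arms))
  if (length(miss)) {
    stop("study pool is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(arms$n <= 0)) stop("study pool contains arms with non-positive n")
  if (any(arms$followup_months <= 0)) {
    stop("study pool contains arms with non-positive follow-up")
  }
  tot <- arms$count_rem + arms$count_lda + arms$count_mhda
  if (any(tot != arms$n)) {
    bad <- arms$study_id[tot != arms$n]
    stop("outcome counts do not sum to n (dropout-corrected denominator) for: ",
         paste(bad, collapse = ", "))
  }
  ok_state <- c("REM", "LDA", "MHDA")
  if (!all(arms$baseline_state %in% ok_state)) {
    stop("baseline_state must be one of ", paste(ok_state, collapse = ", "))
  }
  if (!all(arms$regimen %in% c("standard", "tapering", "withdrawal"))) {
    stop("regimen must be standard, tapering or withdrawal")
  }
  class(arms) <- c("study_pool", "data.frame")
  arms
}

#' Outcome proportions of one study arm
#'
#' Divides the per-state patient counts of an arm by its dropout-corrected
#' denominator.
#'
#' @param arm a single-row data.frame (or list) with fields \code{n},
#'   \code{count_rem}, \code{count_lda}, \code{count_mhda}.
#' @return named numeric vector \code{c(REM=, LDA=, MHDA=)} summing to 1.
#' @export
arm_to_proportions <- function(arm) {
  n <- as.numeric(arm$n)
  if (length(n) != 1L || is.na(n) || n <= 0) stop("arm must have a single positive n")
  counts <- c(REM = as.numeric(arm$count_rem), LDA = as.numeric(arm$count_lda),
              MHDA = as.numeric(arm$count_mhda))
  if (any(counts < 0)) stop("negative outcome count")
  if (sum(counts) != n) stop("outcome counts do not sum to n")
  counts / n
}

#' Rescale a transition probability to a different period length
#'
#' Converts a probability observed over \code{s_months} to the equivalent
#' probability over \code{t_months} through the constant-rate assumption:
#' \deqn{p_r = 1 - (1 - p_s)^{t/s}.}
#'
#' @param p_study probability observed over the study period (in \[0, 1\]).
#' @param s_months study period length in months (> 0).
#' @param t_months target period (model cycle) length in months (> 0).
#' @return the rescaled probability; vectorised over all arguments.
#' @export
rescale_probability <- function(p_study, s_months, t_months) {
  if (any(p_study < 0 | p_study > 1, na.rm = TRUE)) {
    stop("p_study must lie in [0, 1]")
  }
  if (any(s_months <= 0) || any(t_months <= 0)) {
    stop("period lengths must be positive")
  }
  1 - (1 - p_study)^(t_months / s_months)
}

#' DerSimonian-Laird random-effects pooling of one transition cell
#'
#' Pools per-study probabilities for one from-state/to-state cell with the
#' moment-based random-effects estimator, using the binomial within-study
#' variance \eqn{v_i = p_i (1 - p_i) / n_i}. Observations with \eqn{p_i \in
#' \{0, 1\}} have zero estimated variance and are excluded from the cell
#' before pooling (no continuity correction); this exclusion rule is what
#' reproduces the published pooled estimates. The between-study variance is
#' \eqn{\tau^2 = \max(0, (Q - df) / C)} with \eqn{Q} the fixed-effect
#' heterogeneity statistic and \eqn{C = \sum w - \sum w^2 / \sum w}.
#'
#' @param p numeric vector of per-study probabilities.
#' @param n numeric vector of per-study denominators.
#' @param tau2 optional fixed between-study variance overriding the moment
#'   estimate (diagnostic use, e.g. probing the \eqn{\tau^2 \to \infty}
#'   unweighted limit).
#' @return an object of class \code{transition_cell}: a list with
#'   \code{pooled_p}, \code{ci_low}, \code{ci_high} (normal-approximation 95
#'   percent interval, reported but not used downstream), \code{tau2},
#'   \code{k_included} and \code{k_excluded}.
#' @export
pool_cell <- function(p, n, tau2 = NULL) {
  if (length(p) == 0L) stop("pool_cell needs at least one observation")
  if (length(p) != length(n)) stop("p and n must have equal length")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(n <= 0)) stop("denominators must be positive")
  v <- p * (1 - p) / n
  keep <- v > 0
  k_excluded <- sum(!keep)
  p <- p[keep]; v <- v[keep]
  out <- list(pooled_p = 0, ci_low = NA_real_, ci_high = NA_real_,
              tau2 = 0, k_included = length(p), k_excluded = k_excluded)
  if (length(p) == 0L) {
    class(out) <- "transition_cell"
    return(out)
  }
  if (length(p) == 1L) {
    out$pooled_p <- unname(p)
    se <- sqrt(unname(v))
  } else {
    w <- 1 / v
    p_fe <- sum(w * p) / sum(w)
    Q <- sum(w * (p - p_fe)^2)
    df <- length(p) - 1
    C <- sum(w) - sum(w^2) / sum(w)
    if (is.null(tau2)) tau2 <- max(0, (Q - df) / C)
    w_re <- 1 / (v + tau2)
    out$pooled_p <- sum(w_re * p) / sum(w_re)
    out$tau2 <- tau2
    se <- sqrt(1 / sum(w_re))
  }
  out$ci_low <- max(0, out$pooled_p - 1.959964 * se)
  out$ci_high <- min(1, out$pooled_p + 1.959964 * se)
  class(out) <- "transition_cell"
  out
}

#' @export
print.transition_cell <- function(x, ...) {
  cat(sprintf("pooled p = %.4f [%.4f, %.4f], tau2 = %.5f, k = %d (%d excluded)\n",
              x$pooled_p, x$ci_low, x$ci_high, x$tau2, x$k_included, x$k_excluded))
  invisible(x)
}

# per-arm per-cycle probabilities for one regimen/baseline stratum.
# Off-diagonal (state-changing) probabilities are rescaled to the cycle
# length; the staying probability is taken as their complement, matching the
# published transformation. In strict mode the published per-cycle values are
# ingested verbatim from the trans_* columns.
arm_cycle_probs <- function(arms, cycle_months, mode) {
  stay <- arms$baseline_state[1]
  out <- matrix(NA_real_, nrow(arms), 3, dimnames = list(NULL, c("REM", "LDA", "MHDA")))
  if (mode == "strict") {
    if (!all(c("trans_rem", "trans_lda", "trans_mhda") %in% names(arms))) {
      stop("strict pooling mode needs trans_rem/trans_lda/trans_mhda columns")
    }
    out[, "REM"] <- arms$trans_rem
    out[, "LDA"] <- arms$trans_lda
    out[, "MHDA"] <- arms$trans_mhda
    return(out)
  }
  for (i in seq_len(nrow(arms))) {
    prop <- arm_to_proportions(arms[i, ])
    off <- setdiff(colnames(out), stay)
    resc <- rescale_probability(prop[off], arms$followup_months[i], cycle_months)
    out[i, off] <- resc
    out[i, stay] <- max(0, 1 - sum(resc))
  }
  out
}

#' Build pooled, cycle-standardised transition rows from a study pool
#'
#' Runs the three-step estimation: per-arm outcome proportions, rescaling of
#' the state-changing probabilities to the model cycle length (the staying
#' probability is the complement), and DerSimonian-Laird pooling per
#' destination cell. Each row is then normalised to sum to one (pooled cells
#' are estimated independently, so raw rows need not be stochastic).
#'
#' Two modes are available. \code{"recompute"} derives everything from the
#' raw outcome counts. \code{"strict"} instead pools the published per-cycle
#' probabilities carried in the \code{trans_*} columns verbatim; this is the
#' mode that reproduces the published pooled estimates, some of which cannot
#' be re-derived from the counts (the discrepant arms are reported via
#' \code{message()} when both sources are present).
#'
#' @param arms a \code{study_pool} data.frame (see [read_study_pool()]).
#' @param cycle_months model cycle length in months.
#' @param mode \code{"strict"} or \code{"recompute"}.
#' @return a \code{data.frame} of class \code{transition_rows} with one line
#'   per (regimen, from_state, to_state): \code{pooled_p}, \code{ci_low},
#'   \code{ci_high}, \code{tau2}, \code{k_included} and the row-normalised
#'   \code{normalized_p}.
#' @export
build_transition_rows <- function(arms, cycle_months = 6,
                                  mode = c("strict", "recompute")) {
  mode <- match.arg(mode)
  arms <- validate_study_pool(as.data.frame(arms))
  strata <- unique(arms[, c("regimen", "baseline_state")])
  res <- list()
  for (i in seq_len(nrow(strata))) {
    reg <- strata$regimen[i]; from <- strata$baseline_state[i]
    sub <- arms[arms$regimen == reg & arms$baseline_state == from, ]
    probs <- arm_cycle_probs(sub, cycle_months, mode)
    if (mode == "recompute" && all(c("trans_rem", "trans_lda", "trans_mhda") %in% names(sub))) {
      printed <- cbind(sub$trans_rem, sub$trans_lda, sub$trans_mhda)
      bad <- which(rowSums(abs(printed - probs) > 5e-4) > 0)
      for (b in bad) {
        message(sprintf(
          "arm %s (%s/%s): recomputed per-cycle probabilities differ from the published values",
          sub$study_id[b], reg, from))
      }
    }
    cells <- lapply(colnames(probs), function(to) pool_cell(probs[, to], sub$n))
    pooled <- vapply(cells, `[[`, numeric(1), "pooled_p")
    res[[length(res) + 1L]] <- data.frame(
      regimen = reg, from_state = from, to_state = colnames(probs),
      pooled_p = pooled,
      ci_low = vapply(cells, `[[`, numeric(1), "ci_low"),
      ci_high = vapply(cells, `[[`, numeric(1), "ci_high"),
      tau2 = vapply(cells, `[[`, numeric(1), "tau2"),
      k_included = vapply(cells, function(x) as.numeric(x$k_included), numeric(1)),
      normalized_p = pooled / sum(pooled),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "cycle_months") <- cycle_months
  attr(out, "mode") <- mode
  class(out) <- c("transition_rows", "data.frame")
  out
}

#' Extract normalised rows as a named list for the model engine
#'
#' @param rows a \code{transition_rows} data.frame.
#' @return named list keyed \code{"regimen.from_state"} of numeric vectors
#'   \code{c(REM=, LDA=, MHDA=)} summing to 1.
#' @export
transition_row_list <- function(rows) {
  keys <- unique(paste(rows$regimen, rows$from_state, sep = "."))
  out <- lapply(keys, function(k) {
    sub <- rows[paste(rows$regimen, rows$from_state, sep = ".") == k, ]
    stats::setNames(sub$normalized_p, sub$to_state)[c("REM", "LDA", "MHDA")]
  })
  names(out) <- keys
  out
}

#' Write pooled transition rows to CSV
#'
#' @param rows a \code{transition_rows} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pooled_csv <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}
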