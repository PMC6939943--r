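#' @keywords internal
new_state <- function(name, activity, dose, tag, row_key,
                      dest_REM, dest_LDA, dest_MHDA) {
  data.frame(name = name, activity = activity, dose = dose, tag = tag,
             row_key = row_key, dest_REM = dest_REM, dest_LDA = dest_LDA,
             dest_MHDA = dest_MHDA, stringsAsFactors = FALSE)
}

# chain of n sustained states (plain first); each "stay" moves one step along
# the chain, the last stay goes to `exit`. Used for de-escalation eligibility
# (6 months sustained REM/LDA), tapering stability before withdrawal, and the
# self-withdrawal clock.
state_chain <- function(names, activity, dose, tag, row_key, exit,
                        dest_other) {
  n <- length(names)
  stay_next <- c(names[-1], exit)
  do.call(rbind, lapply(seq_len(n), function(i) {
    d <- dest_other
    d[activity] <- stay_next[i]
    new_state(names[i], activity, dose,
              if (i == 1) tag else "sustained", row_key,
              d[["REM"]], d[["LDA"]], d[["MHDA"]])
  }))
}

chain_names <- function(base, n, sus_prefix = paste0("S_", base)) {
  if (n == 1) return(base)
  c(base, sus_prefix, if (n > 2) paste0(sus_prefix, "_", 3:n))
}

# core strategy generator; scenario variants (one-time de-escalation,
# self-withdrawal) are expressed as options so every variant shares one
# audited construction path.
make_strategy <- function(name = c("standard", "tapering", "withdrawal",
                                   "taper_then_withdraw"),
                          cycle_months = 6, one_time = FALSE,
                          self_withdraw_years = NULL) {
  name <- match.arg(name)
  if (!cycle_months %in% c(3, 6)) stop("cycle_months must be 3 or 6")
  n_elig <- max(1L, as.integer(round(6 / cycle_months)))

  # full-dose standard-care core; suffix distinguishes the post-relapse copy
  core <- function(sfx, rem_exit, lda_exit) {
    rem_chain <- chain_names(paste0("REM", sfx), n_elig,
                             paste0("S_REM", sfx))
    lda_chain <- chain_names(paste0("LDA", sfx), n_elig,
                             paste0("S_LDA", sfx))
    rbind(
      new_state(paste0("MHDA", sfx), "MHDA", "full", "plain", "standard.MHDA",
                paste0("REM", sfx), paste0("LDA", sfx), paste0("MHDA", sfx)),
      state_chain(rem_chain, "REM", "full", "plain", "standard.REM",
                  exit = rem_exit,
                  dest_other = c(REM = NA, LDA = paste0("LDA", sfx),
                                 MHDA = paste0("MHDA", sfx))),
      state_chain(lda_chain, "LDA", "full", "plain", "standard.LDA",
                  exit = lda_exit,
                  dest_other = c(REM = paste0("REM", sfx), LDA = NA,
                                 MHDA = paste0("MHDA", sfx))))
  }

  sw <- !is.null(self_withdraw_years)
  if (sw) {
    if (!name %in% c("standard", "tapering")) {
      stop("self-withdrawal applies to standard care or tapering only")
    }
    L <- self_withdraw_years * 12 / cycle_months
    if (abs(L - round(L)) > 1e-9) {
      stop("self-withdrawal period is not a whole number of cycles")
    }
    L <- as.integer(round(L))
  }

  # relapse destinations from de-escalated states (full-dose resumption);
  # one-time restriction routes them into the post-relapse copy instead
  pr <- if (one_time) "_PR" else ""
  lda_full <- paste0("LDA", pr)
  mhda_full <- paste0("MHDA", pr)

  if (name == "standard") {
    if (sw) {
      rem_chain <- chain_names("REM", L)
      sts <- rbind(
        new_state("MHDA", "MHDA", "full", "plain", "standard.MHDA",
                  "REM", "LDA", "MHDA"),
        state_chain(rem_chain, "REM", "full", "plain", "standard.REM",
                    exit = "WD_REM",
                    dest_other = c(REM = NA, LDA = "LDA", MHDA = "MHDA")),
        state_chain(chain_names("LDA", n_elig), "LDA", "full", "plain",
                    "standard.LDA", exit = utils::tail(chain_names("LDA", n_elig), 1),
                    dest_other = c(REM = "REM", LDA = NA, MHDA = "MHDA")),
        new_state("WD_REM", "REM", "zero", "plain", "withdrawal.REM",
                  "WD_REM", "LDA", "MHDA"))
    } else {
      rem_chain <- chain_names("REM", n_elig)
      lda_chain <- chain_names("LDA", n_elig)
      sts <- core("", rem_exit = utils::tail(rem_chain, 1),
                  lda_exit = utils::tail(lda_chain, 1))
    }
  } else if (name == "tapering") {
    tp_rem_chain <- if (sw) chain_names("TP_REM", L, "TP_REM_SW") else "TP_REM"
    sts <- rbind(
      core("", rem_exit = "TP_REM", lda_exit = "TP_LDA"),
      state_chain(tp_rem_chain, "REM", "half", "plain", "tapering.REM",
                  exit = if (sw) "WD_REM" else "TP_REM",
                  dest_other = c(REM = NA, LDA = lda_full, MHDA = mhda_full)),
      new_state("TP_LDA", "LDA", "half", "plain", "tapering.LDA",
                "TP_REM", "TP_LDA", mhda_full))
    if (sw) sts <- rbind(sts,
      new_state("WD_REM", "REM", "zero", "plain", "withdrawal.REM",
                "WD_REM", "LDA", "MHDA"))
  } else if (name == "withdrawal") {
    sts <- rbind(
      core("", rem_exit = "WD_REM", lda_exit = "WD_LDA"),
      new_state("WD_REM", "REM", "zero", "plain", "withdrawal.REM",
                "WD_REM", lda_full, mhda_full),
      new_state("WD_LDA", "LDA", "zero", "plain", "withdrawal.LDA",
                "WD_REM", "WD_LDA", mhda_full))
  } else { # taper_then_withdraw
    tp_chain <- chain_names("TP_REM", n_elig, "S_TP_REM")
    tl_chain <- chain_names("TP_LDA", n_elig, "S_TP_LDA")
    sts <- rbind(
      core("", rem_exit = "TP_REM", lda_exit = "TP_LDA"),
      state_chain(tp_chain, "REM", "half", "plain", "tapering.REM",
                  exit = "WD_REM",
                  dest_other = c(REM = NA, LDA = lda_full, MHDA = mhda_full)),
      state_chain(tl_chain, "LDA", "half", "plain", "tapering.LDA",
                  exit = "WD_LDA",
                  dest_other = c(REM = "TP_REM", LDA = NA, MHDA = mhda_full)),
      new_state("WD_REM", "REM", "zero", "plain", "withdrawal.REM",
                "WD_REM", lda_full, mhda_full),
      new_state("WD_LDA", "LDA", "zero", "plain", "withdrawal.LDA",
                "WD_REM", "WD_LDA", mhda_full))
    sts$tag[sts$name %in% c("S_TP_REM", "S_TP_LDA")] <- "sustained_tapering"
  }

  if (one_time && name != "standard") {
    post <- core("_PR", rem_exit = utils::tail(chain_names("REM_PR", n_elig, "S_REM_PR"), 1),
                 lda_exit = utils::tail(chain_names("LDA_PR", n_elig, "S_LDA_PR"), 1))
    post$tag <- "post_relapse"
    sts <- rbind(sts, post)
  }

  rownames(sts) <- NULL
  spec <- structure(list(name = name, cycle_months = cycle_months,
                         one_time = one_time,
                         self_withdraw_years = self_withdraw_years,
                         states = sts, start_state = "MHDA"),
                    class = "strategy_spec")
  unknown <- setdiff(unlist(sts[, c("dest_REM", "dest_LDA", "dest_MHDA")]),
                     sts$name)
  if (length(unknown)) stop("internal: unknown destination states ",
                            paste(unknown, collapse = ", "))
  spec
}

#' Build a treatment strategy's state machine
#'
#' Constructs the health-state machine for one of the four strategies:
#' \describe{
#'   \item{standard}{full-dose bDMARD care throughout.}
#'   \item{tapering}{immediate 50\% bDMARD dose reduction after sustained
#'     remission or low disease activity.}
#'   \item{withdrawal}{immediate 100\% dose reduction after the same
#'     eligibility.}
#'   \item{taper_then_withdraw}{tapering first, withdrawal after a further
#'     six stable months tapered.}
#' }
#' Eligibility for de-escalation requires six months of sustained
#' remission-class (or LDA-class) activity, encoded as a tunnel of sustained
#' states (two cycles at a 3-month cycle length, one at 6 months). Relapse
#' from any de-escalated state returns the patient to full-dose care, with
#' no limit on re-de-escalation. Death is reachable from every alive state
#' and absorbing.
#'
#' @param name strategy name.
#' @param cycle_months model cycle length (3 or 6 months).
#' @return an object of class \code{strategy_spec}: the state table (name,
#'   activity class, bDMARD dose, tag, pooled-row key and destination map)
#'   plus metadata.
#' @export
build_strategy <- function(name = c("standard", "tapering", "withdrawal",
                                    "taper_then_withdraw"),
                           cycle_months = 6) {
  make_strategy(match.arg(name), cycle_months)
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("strategy '%s' (%d-month cycles): %d alive states + death\n",
              x$name, x$cycle_months, nrow(x$states)))
  if (x$one_time) cat("  variant: one-time de-escalation\n")
  if (!is.null(x$self_withdraw_years)) {
    cat(sprintf("  variant: self-withdrawal after %s years\n",
                x$self_withdraw_years))
  }
  print(x$states[, c("name", "activity", "dose", "tag", "row_key")])
  invisible(x)
}

#' State names of a strategy (alive states, then DEAD)
#' @param spec a \code{strategy_spec}.
#' @export
strategy_states <- function(spec) c(spec$states$name, "DEAD")

# alive-to-alive disease transition matrix (row-stochastic); mortality is
# layered on top per cycle
disease_matrix <- function(spec, rows) {
  st <- spec$states
  ns <- nrow(st)
  missing_rows <- setdiff(unique(st$row_key), names(rows))
  if (length(missing_rows)) {
    stop("missing pooled transition rows for strata: ",
         paste(missing_rows, collapse = ", "))
  }
  D <- matrix(0, ns, ns, dimnames = list(st$name, st$name))
  for (i in seq_len(ns)) {
    row <- rows[[st$row_key[i]]]
    if (abs(sum(row) - 1) > 1e-8) {
      stop("pooled row ", st$row_key[i], " is not normalised")
    }
    dests <- c(st$dest_REM[i], st$dest_LDA[i], st$dest_MHDA[i])
    for (j in 1:3) D[i, dests[j]] <- D[i, dests[j]] + row[j]
  }
  D
}

#' Assemble the full per-cycle transition matrix of a strategy
#'
#' Layers mortality onto the disease dynamics: each alive state first faces
#' its severity-class death probability for the cycle, and the remaining
#' probability mass is split across disease destinations according to the
#' state's pooled regimen row. The death state is absorbing.
#'
#' @param spec a \code{strategy_spec}.
#' @param rows named list of normalised pooled rows
#'   (see [transition_row_list()]).
#' @param mortality a [mortality_model()].
#' @param cycle_index zero-based cycle index.
#' @return a row-stochastic matrix over \code{c(states, "DEAD")}.
#' @export
assemble_matrix <- function(spec, rows, mortality, cycle_index = 0) {
  D <- disease_matrix(spec, rows)
  st <- spec$states
  cls <- ifelse(st$activity == "MHDA", "mhda", "rem_lda")
  pd <- vapply(cls, function(cc) {
    cycle_death_probability(mortality, cycle_index, cc, spec$cycle_months)
  }, numeric(1))
  ns <- nrow(st)
  M <- matrix(0, ns + 1, ns + 1,
              dimnames = list(c(st$name, "DEAD"), c(st$name, "DEAD")))
  M[seq_len(ns), seq_len(ns)] <- (1 - pd) * D
  M[seq_len(ns), ns + 1] <- pd
  M[ns + 1, ns + 1] <- 1
  M
}

#' Diagnose a strategy/row combination
#'
#' Reports (as character messages, never an error) states unreachable from
#' the starting state, pooled rows missing from \code{rows}, and
#' absorbing-state violations.
#'
#' @param spec a \code{strategy_spec}.
#' @param rows named list of normalised pooled rows.
#' @return character vector of diagnostics; empty when well-formed.
#' @export
validate_strategy <- function(spec, rows) {
  st <- spec$states
  out <- character()
  missing_rows <- setdiff(unique(st$row_key), names(rows))
  if (length(missing_rows)) {
    out <- c(out, paste("missing pooled row for stratum:", missing_rows))
  }
  # reachability over the disease graph from the start state
  reach <- spec$start_state
  repeat {
    nxt <- unique(unlist(st[st$name %in% reach,
                            c("dest_REM", "dest_LDA", "dest_MHDA")]))
    new <- setdiff(nxt, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  unreachable <- setdiff(st$name, reach)
  if (length(unreachable)) {
    out <- c(out, paste("state unreachable from start:", unreachable))
  }
  dead_exit <- st$name == "DEAD"
  if (any(dead_exit)) out <- c(out, "DEAD listed as an alive state")
  for (k in intersect(unique(st$row_key), names(rows))) {
    if (abs(sum(rows[[k]]) - 1) > 1e-8) {
      out <- c(out, paste("pooled row not normalised:", k))
    }
  }
  out
}

#' Export a strategy's state machine as JSON
#'
#' @param spec a \code{strategy_spec}.
#' @param path optional file; when omitted the JSON string is returned.
#' @export
strategy_to_json <- function(spec, path = NULL) {
  obj <- list(name = spec$name, cycle_months = spec$cycle_months,
              start_state = spec$start_state, states = spec$states)
  js <- jsonlite::toJSON(obj, pretty = TRUE, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
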