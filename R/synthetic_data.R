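#' Transcribed arm-level study pool
#'
#' The 35 trial arms behind the pooled transition probabilities: for each
#' arm the dropout-corrected denominator, the patient counts per
#' disease-activity state at follow-up, and the follow-up duration. The
#' \code{trans_*} columns carry the published per-cycle transition
#' probabilities verbatim (used by the \code{"strict"} pooling mode); a few
#' arms' published values cannot be re-derived from the counts under any
#' period transformation and are flagged by the \code{"recompute"} mode.
#'
#' @return a \code{study_pool} data.frame with 35 rows.
#' @export
table1_studies <- function() {
  arm <- function(study_id, year, substance, group, design, baseline_state,
                  regimen, n, rem, lda, mhda, fu, t_rem, t_lda, t_mhda) {
    data.frame(study_id = study_id, year = year, substance = substance,
               group = group, design = design,
               baseline_state = baseline_state, regimen = regimen,
               n = n, count_rem = rem, count_lda = lda, count_mhda = mhda,
               followup_months = fu, trans_rem = t_rem, trans_lda = t_lda,
               trans_mhda = t_mhda, stringsAsFactors = FALSE)
  }
  out <- rbind(
    # standard care, baseline REM
    arm("Emery", 2014, "ETA", "CG", "RCT", "REM", "standard", 63, 55, 3, 5, 10, 0.8413, 0.0794, 0.0794),
    arm("Tanaka", 2015, "ADA", "CG", "OC", "REM", "standard", 23, 19, 2, 2, 12, 0.9550, 0.0225, 0.0225),
    arm("Haschka", 2016, "TNF", "CG", "RCT", "REM", "standard", 38, 33, 5, 0, 6, 0.8684, 0.1316, 0.0000),
    # standard care, baseline LDA
    arm("Smolen", 2013, "ETA", "CG", "RCT", "LDA", "standard", 181, 134, 32, 15, 12, 0.2862, 0.6925, 0.0214),
    arm("Smolen", 2014, "ADA", "CG", "RCT", "LDA", "standard", 96, 90, 6, 0, 12, 0.5000, 0.5000, 0.0000),
    arm("van Herwaarden", 2015, "ADA, ETA", "CG", "RCT", "LDA", "standard", 59, 48, 6, 5, 9, 0.4287, 0.5422, 0.0291),
    arm("Keystone", 2016, "ETA", "IG", "RCT", "LDA", "standard", 47, 24, 6, 17, 18, 0.1123, 0.8156, 0.0721),
    # standard care, baseline M/HDA
    arm("Kremer", 2005, "ABA", "IG", "RCT", "MHDA", "standard", 99, 17, 12, 70, 3, 0.1717, 0.1212, 0.7071),
    arm("Westhovens", 2006, "INF", "IG", "RCT", "MHDA", "standard", 663, 216, 371, 76, 6, 0.1789, 0.3364, 0.4847),
    arm("Emery", 2008, "ETA", "IG", "RCT", "MHDA", "standard", 221, 132, 38, 51, 12, 0.2034, 0.0461, 0.7505),
    arm("Schiff", 2008, "ABA", "IG", "RCT", "MHDA", "standard", 147, 14, 17, 116, 6, 0.0488, 0.0596, 0.8916),
    arm("Schiff", 2008, "INF", "IG", "RCT", "MHDA", "standard", 152, 20, 20, 112, 6, 0.0681, 0.0681, 0.8638),
    arm("Ruubert-Roth", 2010, "RITU", "IG", "RCT", "MHDA", "standard", 314, 44, 31, 239, 12, 0.0370, 0.0257, 0.9373),
    arm("Kim", 2012, "ETA", "IG", "RCT", "MHDA", "standard", 193, 82, 30, 81, 4, 0.3396, 0.1190, 0.5414),
    arm("Kavanaugh", 2013, "ADA", "IG", "RCT", "MHDA", "standard", 466, 175, 67, 224, 6, 0.2098, 0.0747, 0.7156),
    arm("Smolen", 2013, "ETA", "CG", "RCT", "MHDA", "standard", 757, 525, 152, 80, 9, 0.3258, 0.0720, 0.6022),
    arm("Yoo", 2013, "INF", "IG", "RCT", "MHDA", "standard", 246, 46, 41, 159, 4, 0.1438, 0.1278, 0.7284),
    arm("Yoo", 2013, "INF", "CG", "RCT", "MHDA", "standard", 249, 44, 29, 176, 4, 0.1357, 0.0887, 0.7756),
    arm("Dougados", 2014, "TOC", "IG", "RCT", "MHDA", "standard", 277, 112, 59, 106, 6, 0.2282, 0.1129, 0.6589),
    arm("Horslev-Petersen", 2014, "ADA", "IG", "RCT", "MHDA", "standard", 81, 66, 5, 10, 12, 0.3440, 0.0158, 0.6402),
    arm("Machado", 2014, "ETA", "IG", "RCT", "MHDA", "standard", 269, 70, 61, 138, 6, 0.1399, 0.1207, 0.7394),
    arm("Nam", 2014, "INF", "CG", "RCT", "MHDA", "standard", 55, 22, 7, 26, 4, 0.3338, 0.0971, 0.5847),
    arm("Schiff", 2014, "ABA, ADA", "IG", "RCT", "MHDA", "standard", 274, 138, 51, 85, 12, 0.1606, 0.0502, 0.7892),
    arm("Schiff", 2014, "ABA, ADA", "CG", "RCT", "MHDA", "standard", 269, 137, 64, 68, 12, 0.1630, 0.0657, 0.7713),
    arm("Keystone", 2016, "ETA", "IG", "RCT", "MHDA", "standard", 58, 8, 9, 41, 18, 0.0244, 0.0277, 0.9479),
    # tapering (50% dose), baseline REM
    arm("Haschka", 2016, "TNF", "IG", "RCT", "REM", "tapering", 36, 29, 4, 3, 3, 0.8056, 0.1111, 0.0833),
    arm("Haschka", 2016, "TNF", "IG", "RCT", "REM", "tapering", 27, 25, 0, 2, 3, 0.9259, 0.0000, 0.0741),
    # tapering, baseline LDA
    arm("Smolen", 2013, "ETA", "IG", "RCT", "LDA", "tapering", 175, 121, 38, 16, 12, 0.2547, 0.7216, 0.0237),
    # withdrawal (100% dose reduction), baseline REM
    arm("Emery", 2014, "ETA", "IG", "RCT", "REM", "withdrawal", 65, 43, 8, 14, 3, 0.6615, 0.1231, 0.2154),
    arm("Nam", 2014, "ETA", "IG", "RCT", "REM", "withdrawal", 40, 17, 7, 16, 6, 0.6829, 0.0917, 0.2254),
    arm("Tanaka", 2015, "ADA", "IG", "OC", "REM", "withdrawal", 52, 25, 7, 20, 12, 0.8502, 0.0355, 0.1143),
    arm("Haschka", 2016, "TNF", "IG", "RCT", "REM", "withdrawal", 27, 20, 4, 3, 3, 0.7407, 0.1481, 0.1111),
    # withdrawal, baseline LDA
    arm("Tanaka", 2010, "INF", "IG", "SA", "LDA", "withdrawal", 102, 44, 12, 46, 12, 0.1316, 0.7292, 0.1392),
    arm("Smolen", 2013, "ETA", "IG", "RCT", "LDA", "withdrawal", 141, 58, 26, 57, 12, 0.1241, 0.7545, 0.1215),
    arm("Smolen", 2014, "ADA", "IG", "RCT", "LDA", "withdrawal", 89, 67, 15, 7, 12, 0.2949, 0.6848, 0.0203))
  validate_study_pool(out)
}

#' Published economic parameter set
#'
#' The full parameter table as a nested list: base-case annual costs and
#' utilities, deterministic sensitivity bounds, probabilistic sampling
#' distributions (gamma moments for costs, Dirichlet concentration vectors
#' for transition rows, beta shapes for utilities), mortality settings and
#' run settings. [default_econ_params()] wraps this into the
#' \code{econ_params} object the model consumes; [write_fixtures()] writes
#' it as the \code{table2_params.yaml} fixture.
#'
#' @return a nested list mirroring the published parameter table.
#' @export
table2_params <- function() {
  cost_par <- function(base, low, high, mean, sd) {
    list(base = base, dsa_low = low, dsa_high = high,
         psa = list(dist = "gamma", mean = mean, sd = sd))
  }
  util_par <- function(base, low, high, alpha, beta) {
    list(base = base, dsa_low = low, dsa_high = high,
         psa = list(dist = "beta", alpha = alpha, beta = beta))
  }
  cell <- function(base, low, high) list(base = base, dsa_low = low, dsa_high = high)
  list(
    costs = list(
      bdmard = cost_par(14834, 8147, 21520, 14834, 6687),
      csdmard = cost_par(1086, 596, 1575, 1086, 490),
      concomitant = cost_par(45, 25, 65, 45, 20),
      other_direct = list(
        le64 = list(REM = cost_par(1495, 821, 2168, 1760, 793),
                    LDA = cost_par(2316, 1272, 3360, 2386, 1068),
                    MHDA = cost_par(3713, 2039, 5387, 3797, 1712)),
        gt65 = list(REM = cost_par(2024, 1112, 2936, 1760, 793),
                    LDA = cost_par(2421, 1330, 3512, 2386, 1068),
                    MHDA = cost_par(3881, 2132, 5630, 3797, 1712)))),
    utilities = list(
      REM = util_par(0.75, 0.69, 0.81, 0.7133, 0.2378),
      LDA = util_par(0.71, 0.68, 0.74, 0.8112, 0.3313),
      MHDA = util_par(0.60, 0.57, 0.64, 0.8984, 0.5990),
      decrement_full_dose = 0.0567,
      decrement_half_dose = 0.0284),
    transitions = list(
      standard.REM = list(dirichlet = c(111, 8, 6),
        cells = list(REM = cell(0.8911, 0.8457, 0.9585),
                     LDA = cell(0.0666, 0.0039, 0.0910),
                     MHDA = cell(0.0491, 0.0000, 0.1048))),
      standard.LDA = list(dirichlet = c(126, 245, 10),
        cells = list(REM = cell(0.3291, 0.1702, 0.4879),
                     LDA = cell(0.6390, 0.5079, 0.7700),
                     MHDA = cell(0.0256, 0.0080, 0.0431))),
      standard.MHDA = list(dirichlet = c(843, 429, 3499),
        cells = list(REM = cell(0.1760, 0.1290, 0.2219),
                     LDA = cell(0.0895, 0.0593, 0.1196),
                     MHDA = cell(0.7305, 0.6609, 0.8015))),
      tapering.REM = list(dirichlet = c(55, 7, 5),
        cells = list(REM = cell(0.8733, 0.7562, 0.9903),
                     LDA = cell(0.1111, 0.0085, 0.2138),
                     MHDA = cell(0.0791, 0.0125, 0.1458))),
      tapering.LDA = list(dirichlet = c(45, 126, 5),
        cells = list(REM = cell(0.2547, 0.1946, 0.3148),
                     LDA = cell(0.7216, 0.6598, 0.7834),
                     MHDA = cell(0.0237, 0.0027, 0.0447))),
      withdrawal.REM = list(dirichlet = c(136, 16, 30),
        cells = list(REM = cell(0.7394, 0.6411, 0.8378),
                     LDA = cell(0.0843, 0.0320, 0.1367),
                     MHDA = cell(0.1616, 0.1012, 0.2220))),
      withdrawal.LDA = list(dirichlet = c(59, 243, 30),
        cells = list(REM = cell(0.1764, 0.0871, 0.2656),
                     LDA = cell(0.7322, 0.6897, 0.7746),
                     MHDA = cell(0.0905, 0.0086, 0.1725)))),
    mortality = list(female_share = 0.75, smr_mhda = 2.34, start_age = 45,
                     cycle_one = list(rem_lda = 0.0008, mhda = 0.0019)),
    settings = list(cycle_months = 6, horizon_years = 30,
                    annual_discount_rate = 0.03,
                    discount_dsa = c(0.0, 0.06),
                    horizon_dsa_cycles = c(40, 80)))
}

#' Generate a calibrated synthetic life table
#'
#' Builds a sex-specific annual life table from a Gompertz mortality law
#' \eqn{q(a) = \min(1, c e^{b a})} with a fixed male/female hazard ratio,
#' calibrated so that the sex-weighted per-cycle death probability at the
#' calibration age equals a target value (by default the published
#' cycle-one probability of 0.0008). Only the level is calibrated; the
#' slope is a documented constant chosen as a typical adult mortality
#' doubling time of about 7.7 years. The table is synthetic: it stands in
#' for a national all-cause table, which users may substitute in the same
#' CSV layout.
#'
#' @param target_cycle_prob sex-weighted per-cycle death probability at the
#'   calibration age, in (0, 1).
#' @param cycle_months cycle length the target refers to.
#' @param gompertz_b Gompertz slope per year of age.
#' @param male_female_hr male/female hazard ratio.
#' @param ages integer ages to emit.
#' @param female_share cohort female proportion used in the calibration.
#' @param calib_age calibration age in years.
#' @return a \code{life_table} data.frame.
#' @export
make_life_table <- function(target_cycle_prob = 0.0008, cycle_months = 6,
                            gompertz_b = 0.09, male_female_hr = 1.6,
                            ages = 40:100, female_share = 0.75,
                            calib_age = 45) {
  if (target_cycle_prob <= 0 || target_cycle_prob >= 1) {
    stop("calibration target must lie in (0, 1)")
  }
  q_annual_target <- 1 - (1 - target_cycle_prob)^(12 / cycle_months)
  mix <- female_share + (1 - female_share) * male_female_hr
  a_f <- q_annual_target / (mix * exp(gompertz_b * calib_age))
  if (!is.finite(a_f) || a_f <= 0) stop("infeasible calibration")
  df <- data.frame(age = ages,
                   q_female = pmin(1, a_f * exp(gompertz_b * ages)),
                   q_male = pmin(1, male_female_hr * a_f * exp(gompertz_b * ages)))
  validate_life_table(df)
}

#' Simulate a synthetic study pool around a known transition matrix
#'
#' Generates arm-level outcome counts whose pooled, cycle-standardised
#' transition rows should recover a known truth: for each stratum, each
#' arm's follow-up-specific probabilities are derived from the true
#' per-cycle row by the inverse of the period rescaling (off-diagonals
#' \eqn{p_s = 1 - (1 - p_r)^{s/t}}, staying probability as complement), and
#' counts are drawn multinomially.
#'
#' @param true_rows named list (keys \code{"regimen.from_state"}) of true
#'   per-cycle rows \code{c(REM=, LDA=, MHDA=)} summing to 1.
#' @param arms_per_cell number of arms per stratum.
#' @param n_range range of arm sizes to sample uniformly.
#' @param followup_choices follow-up durations (months) sampled per arm.
#' @param cycle_months cycle length the true rows refer to.
#' @param seed RNG seed (required: pools are meant to be reproducible).
#' @return a \code{study_pool} data.frame.
#' @export
simulate_study_pool <- function(true_rows, arms_per_cell = 5,
                                n_range = c(50, 400),
                                followup_choices = c(3, 6, 9, 12),
                                cycle_months = 6, seed = 42) {
  set.seed(seed)
  res <- list()
  for (key in names(true_rows)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    regimen <- parts[1]; from <- parts[2]
    p_r <- true_rows[[key]]
    if (abs(sum(p_r) - 1) > 1e-8) stop("true row ", key, " does not sum to 1")
    off <- setdiff(c("REM", "LDA", "MHDA"), from)
    for (a in seq_len(arms_per_cell)) {
      s <- followup_choices[sample.int(length(followup_choices), 1)]
      n <- n_range[1] + sample.int(n_range[2] - n_range[1] + 1, 1) - 1
      p_s <- numeric(3); names(p_s) <- c("REM", "LDA", "MHDA")
      p_s[off] <- 1 - (1 - p_r[off])^(s / cycle_months)
      p_s[from] <- max(0, 1 - sum(p_s[off]))
      counts <- as.integer(stats::rmultinom(1, n, p_s))
      res[[length(res) + 1L]] <- data.frame(
        study_id = sprintf("sim_%s_%02d", key, a), year = 2020,
        substance = "SIM", group = "IG", design = "RCT",
        baseline_state = from, regimen = regimen, n = n,
        count_rem = counts[1], count_lda = counts[2],
        count_mhda = counts[3], followup_months = s,
        stringsAsFactors = FALSE)
    }
  }
  validate_study_pool(do.call(rbind, res))
}

#' Write the packaged fixtures to a directory
#'
#' Emits \code{table1_studies.csv} (the transcribed study pool),
#' \code{table2_params.yaml} (the economic parameter set) and
#' \code{lifetable_fixture.csv} (the calibrated synthetic life table). The
#' files round-trip through [read_study_pool()], [read_econ_params()] and
#' [read_life_table()].
#'
#' @param dir target directory (created if missing).
#' @return the three file paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "table1_studies.csv")
  p2 <- file.path(dir, "table2_params.yaml")
  p3 <- file.path(dir, "lifetable_fixture.csv")
  utils::write.csv(as.data.frame(table1_studies()), p1, row.names = FALSE)
  yaml::write_yaml(table2_params(), p2, precision = 12)
  utils::write.csv(as.data.frame(make_life_table()), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
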