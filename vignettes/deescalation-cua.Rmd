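---
title: "Modelling the cost-utility of bDMARD de-escalation in rheumatoid arthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-utility of bDMARD de-escalation in rheumatoid arthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deescra)
```

## The decision problem

Biological DMARDs control rheumatoid arthritis well but cost roughly an
order of magnitude more than everything else in a patient's care combined
(about 14,800 EUR per year at the full dose versus 1,500-3,900 EUR per year
of other direct costs). Treatment guidelines therefore suggest de-escalating
the bDMARD once a patient reaches stable remission or low disease activity.
`deescra` implements a cohort Markov model that quantifies the trade-off
from a payer's perspective for three de-escalation strategies against
continued full-dose care:

* **tapering** — an immediate 50% dose reduction,
* **withdrawal** — an immediate 100% dose reduction,
* **taper-then-withdraw** — tapering first, withdrawal after six further
  stable months on the half dose.

The result of each comparison is a pair of increments (cost, QALYs) per
patient and, because de-escalation in this model saves money *and* loses
quality of life, an ICER read as *savings per QALY lost* (southwest
quadrant of the cost-effectiveness plane).

## Health states and eligibility tunnels

Disease activity is classified by DAS28 into remission (REM, DAS28 < 2.6),
low disease activity (LDA, < 3.2) and medium-to-high disease activity
(M/HDA), plus absorbing death. De-escalation is only offered after **six
months of sustained** REM or LDA. A cohort model has no memory, so the
waiting time is encoded as tunnel states: at 3-month cycles a patient walks
`REM -> S_REM -> TP_REM`; at 6-month cycles one sustained cycle suffices.
The same device encodes the six stable tapered months required before
withdrawal in the taper-then-withdraw strategy (`TP_REM -> S_TP_REM ->
WD_REM`) and the multi-year clocks of the self-withdrawal scenarios.

Relapse from any de-escalated state returns the patient to full-dose care
(plain LDA or M/HDA), and eligibility can be re-earned without limit.
Improvement while de-escalated keeps the reduced dose: `TP_LDA` improves to
`TP_REM`, `WD_LDA` to `WD_REM`. Sustained-state copies carry the dynamics
and costs of their origin state; they change bookkeeping, never totals.

```{r states, eval = FALSE}
build_strategy("taper_then_withdraw", cycle_months = 3)  # 12 states
strategy_to_json(build_strategy("withdrawal", 6))        # audit export
```

## Estimating transition probabilities

Each strategy's per-cycle rows are pooled from arm-level trial results
observed at follow-ups between 3 and 18 months. The three-step procedure:

1. per-arm outcome proportions, `count / n` with dropout-corrected `n`;
2. rescaling of the state-*changing* probabilities to the cycle length via
   the constant-rate transformation `p_r = 1 - (1 - p_s)^(t/s)`, with the
   staying probability as their complement;
3. DerSimonian-Laird random-effects pooling per destination cell, with the
   binomial within-study variance `p(1-p)/n`.

Arms observing `p = 0` or `p = 1` carry an estimated variance of zero and
are excluded from that cell before pooling; this rule (rather than a
continuity correction) is what reproduces the published pooled estimates
such as the 0.0491 remission-to-M/HDA cell, where a zero-event arm drops
out. Pooled cells are estimated independently, so a row need not sum to one
(the standard-care remission row sums to 1.0068); each row is renormalised
proportionally before model use, the minimal correction that preserves the
cells' relative sizes.

Two ingestion modes exist because the source table is not perfectly
self-consistent. `"strict"` (the default) pools the published per-cycle
probabilities verbatim and reproduces the published pooled values.
`"recompute"` re-derives everything from the raw counts with a 3-month
target period, which reproduces the published per-arm values for 32 of the
35 arms; the three irreproducible arms (two standard-care remission control
arms and one M/HDA control arm whose printed row sums to 1.0156) are
flagged with a `message()` rather than an error, and the fixture carries
their printed values for the strict path. The package's own
DerSimonian-Laird implementation is cross-checked in the test suite against
`metafor` and against a step-by-step evaluation of the moment estimator.

## Cycle length: a documented inconsistency, and the package default

The source analysis describes itself once as using 3-month cycles over 120
cycles and elsewhere as using 6-month cycles: its figure caption states
6-month cycles, its parameter table lists a horizon of 60 cycles with
bounds 40/80 (i.e. 30/20/40 years at 6 months), its transition table is
headed "six-month probabilities", and its cycle-one death probability of
0.0008 matches German all-cause mortality at age 45 over six months rather
than three. Reproduction agrees: at 6-month cycles this package lands
within a few percent of all published headline numbers (the tapering ICER
within 0.1%), whereas at 3-month cycles the tapering ICER falls about 20%
short. The package therefore defaults to **6-month cycles, 60 cycles**;
`cycle_months = 3` is fully supported (eligibility tunnels double in
length) and exercised in the tests, for users who prefer the main-text
reading.

## Mortality

A sex-specific annual life table is weighted 3:1 female:male (the sex mix
of German RA patients), converted to the cycle length by compound survival,
and multiplied by a standardised mortality ratio of 2.34 for patients in
M/HDA — applied to the per-cycle probability (capped at 1), which is the
reading that reproduces the published M/HDA cycle-one value of 0.0019 =
0.0008 x 2.34. Attained age is floored to index the annual table; within
each cycle's matrix row the disease transitions share the survival mass
`1 - p_death`.

No WHO table ships with the package. [make_life_table()] generates a
**synthetic** Gompertz table `q(a) = min(1, c e^{0.09 a})` whose level is
calibrated so the weighted per-cycle probability at age 45 equals 0.0008;
the slope 0.09/yr corresponds to a typical adult mortality doubling time of
about 7.7 years, and a fixed male/female hazard ratio of 1.6 keeps the sex
weighting non-trivial. The calibration pins early-cohort mortality, which
dominates the discounted results; old-age mortality is Gompertz
extrapolation, one reason the headline comparison carries a tolerance band
rather than exact expectations. Users can substitute a real national table
in the same CSV layout.

## Costs, utilities, discounting

Annual state costs are `other_direct(activity, age band) + csDMARD +
concomitant + bDMARD x dose fraction` with dose fractions 1, 0.5 and 0;
the age band switches when attained age reaches 65 (cycle 40 from age 45
at 6-month cycles). Utilities depend on the activity class alone: 0.75,
0.71, 0.60, death 0. QALYs accrue as utility x cycle length in years;
costs as annual cost x cycle length. Both streams are valued on the
trapezoid (half-cycle correction: adjacent occupancy rows averaged) and
discounted at an effective 3% per annum, cycle *k* by `(1+r)^(-k m/12)`.
The per-cycle-accrual reading of "utilities per cycle" (which would double
QALYs at 6-month cycles) is exposed only as the diagnostic toggle
`qaly_cycle_scaling` in [run_settings()].

```{r base, eval = FALSE}
model <- deesc_model()          # packaged study pool + calibrated life table
run_base_case(model)
```

## Sensitivity analyses

**Deterministic (tornado).** Every cost (bounds of +/-45%), utility
(published confidence bounds), pooled transition cell (pooling confidence
bounds), the discount rate (0-6%) and the horizon (40/80 cycles, rerun
structurally) is varied one at a time. A perturbed transition cell is set
to its bound and the row renormalised proportionally, preserving the
composition of the remaining cells. Results are ordered by the
incremental-cost swing.

**Probabilistic.** Monte Carlo over: gamma costs parameterised from the
published (mean, sd) via `shape = (mean/sd)^2`, `scale = sd^2/mean`;
Dirichlet transition rows drawn from the published concentration vectors
and used directly as rows (their means differ slightly from the pooled
point estimates — e.g. 111/125 = 0.888 vs 0.8911 — mirroring the source,
whose base case and PSA inputs differ the same way); beta utilities from
the published shapes. The REM beta(0.7133, 0.2378) has mean 0.75 but a
standard deviation near 0.31 — enormous for a utility, implemented as
published. Parameters are sampled independently; no correlation structure
is described. All randomness flows from a single seed and runs are
bit-reproducible. The acceptability curve reports, per threshold, the share
of draws with positive net monetary benefit `lambda * dQALY - dCost`.

**Scenarios.** (a) bDMARD side-effect utility decrements (0.0567 at the
full dose, 0.0284 tapered, none withdrawn) — under which tapering becomes
dominant; (b) self-withdrawal of the bDMARD after 2/3/5 years of stable
remission, modelled as a remission-cycle tunnel under standard care and —
counting tapered-remission cycles — under tapering (a flag restricts the
modification to standard care, since the source is ambiguous about the
comparator); (c) one-time de-escalation eligibility via post-relapse state
copies with standard-care dynamics and no route back; (d) horizons of
5/10/20/40 years. Each scenario collapses to the base model when its
distinguishing parameter is neutralised (zero decrements, unreachable
remission, zero relapse), which the tests assert bit-identically.

## Numerical choices and degenerate inputs

* Row normalisation tolerance 1e-12; trace conservation asserted at 1e-8
  on a cohort of 1,000.
* `p = 1` passes through the period transformation by continuity.
* A stratum with every observation excluded pools to 0 with `k = 0`; a
  single surviving observation passes through with `tau2 = 0`.
* `tau2` truncates at zero when the heterogeneity statistic falls below
  its degrees of freedom, collapsing onto the fixed-effect mean.
* The DL normal-approximation interval is reported but **not** used as DSA
  bounds — it does not reproduce the published asymmetric bounds, which
  are taken as given from the parameter table.
* The SMR cap `min(1, q x SMR)` never binds before age 100 with the
  packaged table.

## Problem sizes used by the packaged checks

The test suite runs the full 60-cycle model everywhere, the complete
scenario grid, and a 10,000-iteration PSA (about half a minute); pooling
recovery uses simulated pools of 20 arms x n = 5,000 over five seeds with
a mean per-cell bias bound of 0.01. The acceptance script recomputes only
deterministic quantities and runs in seconds.

## Known limitations

* Two published pooled cells (0.0491 and 0.7394) differ in the fourth
  decimal from exact DL pooling of the published inputs (0.0492, 0.7396);
  the source appears to have pooled intermediate values at different
  precision. The package reports its exactly-computed values.
* The synthetic life table reproduces calibrated young-adult mortality,
  not any particular national table; survival beyond ~80 is extrapolation.
* No treatment sequencing, no second-line biologics, no adverse-event
  states, no societal costs, and medium and high disease activity are
  merged — all inherited from the evidence base.
* Simulated study pools draw multinomial counts under the constant-rate
  assumption that the model itself uses; recovery tests therefore validate
  the estimation machinery, not that assumption.
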