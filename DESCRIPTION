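Package: deescra
Title: Cost-Utility Modelling of Biologic DMARD De-Escalation in Rheumatoid Arthritis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort Markov model for evaluating strategies that de-escalate
    biological disease-modifying anti-rheumatic drugs (bDMARDs) in rheumatoid
    arthritis patients who reach remission or low disease activity. Provides
    random-effects (DerSimonian-Laird) pooling of arm-level transition
    probabilities observed at heterogeneous follow-up durations, tunnel-state
    state machines for standard care, tapering, withdrawal and tapering
    followed by withdrawal, a discounted half-cycle-corrected cohort trace
    with age-, sex-mix- and severity-adjusted mortality, incremental
    cost-utility results, and deterministic (tornado), probabilistic (Monte
    Carlo with gamma/Dirichlet/beta sampling) and structural scenario
    sensitivity analyses including cost-effectiveness acceptability curves.
    Ships a transcription of the published study pool and economic parameter
    set, plus a synthetic life-table and study-pool generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
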