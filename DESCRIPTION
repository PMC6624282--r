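Package: thermolba
Title: Hierarchical Linear Ballistic Accumulator Modeling of Choice Under
    Deadlines with a Temperature-Driven Clock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how a speeded internal clock
    changes decision making under response deadlines.  Provides a synthetic
    study generator emulating an interval-reproduction task and a
    two-alternative flicker-discrimination task across water-temperature
    conditions and measurement moments; the Linear Ballistic Accumulator
    (LBA) likelihood kernel with defective densities and the additive-urgency
    / collapsing-threshold equivalence; three hierarchical model variants
    with uniform participant-level and gamma hyper-variance priors; a
    differential-evolution MCMC sampler with crossover and migration moves,
    Gelman-Rubin diagnostics and stuck-chain detection; BPIC model comparison
    with posterior-predictive defective CDFs; and the behavioral
    preprocessing pipeline (fast-RT exclusion, log-RT, baseline z-scoring,
    cross-task change correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
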