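# thermolba

Hierarchical Linear Ballistic Accumulator (LBA) modeling of choice under
response deadlines, coupled to a temperature-driven internal clock.

## The problem

Deciding under a deadline requires a sense of elapsed time.  This package
implements the computational analysis of a within-participant design that
manipulates the internal clock directly: participants are immersed in warm
water (passive hyperthermia, Warm condition, 38 °C) or thermoneutral water
(Neutral, 36 °C), and perform two tasks at an out-of-tub Baseline and at the
Begin and End of each session — reproducing a learned 1 s interval, and
discriminating which of two flickering circles flickers at the higher rate
(Bernoulli rates 0.7 vs 0.3) within a 1 s deadline.  A faster pacemaker
makes the learned interval feel complete sooner (underproduction) and, if
the same clock times the deadline, should lower decision thresholds or
raise urgency late in the Warm session.

The original participant data are available only on request, so the package
includes a first-class synthetic-study generator with known ground truth;
every stage of the pipeline is developed and tested against it.

## What is inside

* **LBA kernel** (`accumulator_cdf`, `accumulator_pdf`, `defective_pdf`,
  `choice_prob`, `trial_loglik`, `collapse_equivalent`): closed-form
  crossing-time distributions; un-normalized defective densities for
  two-choice data with the drift difference parametrization
  (Δv = v_correct − v_error, B = b − A, s_correct = 1); the exact
  equivalence of additive urgency and a linearly collapsing threshold.
* **Hierarchical models** (`build_model`, `prior_spec`,
  `log_prior_participant`, `log_hyperprior`, `dataset_loglik`): three
  variants letting drift, threshold gap B, or both vary across the six
  design cells, with A, s_error, t0, Δv shared; uniform participant-level
  priors, uniform hypermean priors, Gamma(1, 1) hyperSD priors.
* **DE-MCMC sampler** (`run_sampler`, `demcmc_sample`, `crossover_update`,
  `migration_update`, `psrf`, `hier_psrf`, `detect_stuck`): D = 3 × the
  parameter count chains, crossover weight 2.38/√D (participant level) and
  U[0.5, 1] (group level), perturbation ±0.001, migration probability 0.05
  during a 1,000-iteration burn-in, ≥5,000 sampling iterations with
  immediate thinning by 5; Gelman–Rubin univariate and Brooks–Gelman
  multivariate diagnostics; stuck-chain detection with influence reports.
* **Model selection** (`deviance_summaries`, `compare_models`,
  `posterior_predictive_cdf`): BPIC = mean deviance + 2·pD with a same-data
  hash guard, and posterior-predictive defective CDF summaries.
* **Behavior pipeline** (`read_trials`, `write_trials`, `filter_fast_rts`,
  `log_transform_rts`, `baseline_zscore`, `accuracy_measures`,
  `correlate_changes`, `preprocess_trials`): validated CSV dialect,
  strict < 200 ms exclusion, log-RTs, per-session baseline z-scores, and
  cross-task change correlations.
* **Synthetic study** (`generate_study`, `study_truth`, `clock_params`,
  `simulate_reproductions`, `simulate_flicker`, `simulate_choices`):
  pacemaker-clock reproductions, Bernoulli flicker stimuli, LBA choices,
  and per-participant coupling between clock speed-up and threshold drop.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate_study.R` … `05_correlations.R`) that run the pipeline end to
end and write tables under `results/`.

## Worked example

```r
library(thermolba)

study <- generate_study(study_truth(), n_participants = 6,
                        n_trials_per_cell = 80, seed = 7,
                        cells = c("Warm:Baseline", "Warm:End"))
prep <- preprocess_trials(as_trial_table(study))
choice <- prep$trials[prep$trials$task == "choice", ]

model <- build_model("threshold_only", c("Warm:Baseline", "Warm:End"))
model
#> Hierarchical LBA model 'threshold_only': 2 cells, 7 participant-level parameters, D = 21 chains
#>   free across cells: B
#>   shared: v_correct, delta_v, s_error, A, t0

fit <- run_sampler(choice, model,
                   config = sampler_config(n_burn = 400, n_sample = 800,
                                           thin = 5, seed = 1))
fit
#> Hierarchical LBA fit (threshold_only): 6 participants, 21 chains, 160 retained iterations
#>   acceptance: participant 0.163, group 0.307; 158 migration sweeps

round(group_posterior_means(fit)$mean, 3)
#>       v_correct         delta_v         s_error               A              t0
#>           3.498           2.031           1.176           0.428           0.084
#> B|Warm:Baseline      B|Warm:End
#>           1.429           1.296
```

For this dataset the realized group truth is v 3.12, Δv 2.02, s 1.07,
A 0.65, t0 0.17, B 0.91 at Warm:Baseline dropping to 0.77 at Warm:End.
The drift parameters recover closely, and the fitted threshold gap `B` is
lower at Warm:End than at Warm:Baseline — the generated coupling effect —
while `A` and `t0` sit low and `B` high: those three trade off along a
notoriously flat likelihood ridge in this model, and at this deliberately
short illustrative schedule the posterior has not fully spread along it.
The vignette discusses this identifiability structure and the schedules
used for real inference runs.

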