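---
title: "Modeling choice under deadlines with a temperature-driven clock: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling choice under deadlines with a temperature-driven clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolba)
```

## The scientific problem

When people must decide under a deadline, they trade accuracy for speed;
doing so sensibly requires a sense of how much time has passed.  The
experimental design this package models couples the two abilities within
participants: an interval-reproduction task measures the internal clock,
and a two-alternative flicker-discrimination task with a 1 s response
deadline measures decision behavior, both administered at an out-of-tub
Baseline and at the Begin and End of Neutral (36 °C) and Warm (38 °C)
water-immersion sessions.  Passive hyperthermia is hypothesized to speed
the internal pacemaker: a learned 1 s interval then feels complete
sooner (underproduction), and — if the same clock feeds the decision
system's sense of deadline proximity — choices under time pressure
should show lowered thresholds or elevated urgency at the End of the
Warm session.

The participant data of the original study are not publicly deposited,
so the package pairs the full analysis pipeline with a synthetic-data
generator that emulates the design and its hypothesized effect
structure.  Everything downstream — preprocessing, hierarchical model
fitting, model comparison, correlational analyses — is exercised and
tested against data whose ground truth is known.

## The LBA kernel

Each response option is a linear ballistic accumulator: on a trial the
accumulator for option $k$ starts at a point drawn uniformly from
$[0, A]$, accrues evidence at a constant rate drawn from
$\mathcal{N}(v_k, s_k)$, and the first accumulator to reach the
threshold $b$ determines the response, at time $t_0 + (b - a_0)/d$.
Estimation uses the gap $B = b - A$ rather than $b$, the drift of the
correct accumulator $v_\mathrm{correct}$ and the difference
$\Delta v = v_\mathrm{correct} - v_\mathrm{error}$, and fixes
$s_\mathrm{correct} = 1$ as the scaling constraint (the model is
invariant to a common rescaling of $A, B, v, s$; `choice_prob()`'s
scale-invariance test exercises exactly this).

The closed-form crossing-time distribution of a single accumulator
(`accumulator_cdf()`, `accumulator_pdf()`) combines with the
competitor's survival function into the defective density
$f_k(t)\,(1 - F_{k'}(t))$ of observing response $k$ at time $t$
(`defective_pdf()`).  Densities are un-normalized: we do not divide by
the probability that at least one drift is positive, matching the
common estimation convention for this model family; the neglected mass
(`all_negative_mass()`) is below $10^{-3}$ everywhere near the fitted
parameter ranges and is reported as a diagnostic.  Densities are
floored at $10^{-300}$ before logs so only genuinely impossible
observations ($t \le t_0$) yield $-\infty$.

An additive urgency component $u$ on all drifts is mathematically
identical, for a ballistic accumulator, to a threshold that collapses
linearly at rate $u$: for shared start point and drift draw,
$(b - a_0)/(d + u)$ solves both parameterizations.
`collapse_equivalent()` returns both forms and per-draw crossing-time
evaluators; the equivalence is checked draw-by-draw and by
shared-randomness simulation in the test suite.  Because of this
identity, the drift rate estimated below is always the sum of stimulus
evidence and urgency; the two are not separately identifiable in this
design.

## Hierarchical model variants and priors

Three variants differ in what may vary across the six design cells
(condition × moment): the drift rate, the threshold gap $B$, or both.
$A$, $s_\mathrm{error}$, $t_0$ and $\Delta v$ are always shared across
cells.  Participant-level parameters have the wide uniform priors

| parameter | participant prior | hypermean prior |
|---|---|---|
| $v_\mathrm{correct}$ | U(−5, 20) | U(0, 10) |
| $\Delta v$ | U(0, 20) | U(0, 10) |
| $s_\mathrm{error}$ | U(0.1, 10) | U(0.1, 5) |
| $A$ | U(0.01, 20) | U(0.01, 10) |
| $B$ | U(0.01, 20) | U(0.01, 10) |
| $t_0$ | U(0.01, 0.5) s | U(0.01, 0.5) s |

with Gamma(1, 1) priors on every hyperSD.  The group-level family is
not pinned down by the printed prior table beyond "hypermeans and
hyperSDs"; we adopt a normal distribution truncated to the
participant-level uniform support, which keeps participant priors
proper and is the standard choice in this estimation toolbox family.
This is an assumption, and it is the one place the prior specification
goes beyond what is printed.

## The DE-MCMC sampler

The number of chains is $D = 3 \times$ (participant-level parameter
count).  Each iteration updates, in turn, every participant's parameter
block conditional on that participant's data and the chain's
group-level parameters, then the group level conditional on all
participants.  Proposals are differential-evolution crossovers —
current position plus $\gamma$ times the difference of two other
chains' positions plus a uniform perturbation on $[-0.001, 0.001]$ —
with $\gamma = 2.38/\sqrt{D}$ at the participant level and
$\gamma \sim U[0.5, 1]$ per move at the group level, accepted by
Metropolis–Hastings.  During the 1,000-iteration burn-in each block
instead performs, with probability 0.05, a migration sweep in which a
random ring of chains exchange states.  Sampling runs for at least
5,000 iterations with immediate thinning by 5.

Design choices the scheme leaves open, and how this implementation
resolves them:

* **Update order.** Chains are updated sequentially with live donors
  (accepted moves immediately available to later proposals), the form
  for which detailed balance of the population sampler is established.
  A chain-parallel variant with block-start donors was measured and
  mixed consistently worse here; it is not used.
* **Group blocking.** The group block updates one (hypermean, hyperSD)
  pair at a time.  A joint proposal over all pairs at once had a few
  percent acceptance and mixed far too slowly; per-pair sub-blocks
  accept around 30% and mix an order of magnitude better.
* **Initialization.** Chain starts are drawn from the participant-level
  priors (best finite-posterior draw of 20 per chain), so starts are
  overdispersed and the Gelman–Rubin diagnostic retains its usual
  interpretation.  A faster `"jitter"` mode that scatters chains around
  a rough likelihood mode exists for exploratory work, but it
  under-represents posterior spread along weakly identified directions
  (see "Identifiability" below) and is not used for inference.
* **Support violations** are rejected (posterior $-\infty$), not
  reflected; **migration ring size** is uniform on $\{1, \dots, D\}$;
  thinning is applied while sampling, so only the retained buffer is
  ever stored, along with the per-sample data log-likelihoods that make
  deviance summaries exact afterwards.

Convergence is summarized by the Brooks–Gelman multivariate potential
scale reduction factor computed per participant and medianed
(`hier_psrf()`), with the conventional 1.05 threshold; univariate
R-hat values and a group-level statistic are also reported.  A chain
that accepts no proposal over a long window is flagged by
`detect_stuck()`, which reports posterior summaries with and without
the flagged chains so their influence can be judged rather than
guessed.

## Model comparison and posterior predictives

`deviance_summaries()` computes the mean posterior deviance $\bar D$
from the stored per-sample log-likelihoods and the deviance at the
posterior mean $D(\bar\theta)$; the effective parameter count is
$p_D = \bar D - D(\bar\theta)$ by default (a minimum-deviance variant
is available behind a flag) and $\mathrm{BPIC} = \bar D + 2 p_D$.
Fits are compared only when their recorded data hashes agree, so a
variant can never be ranked against a fit of different trials.
`posterior_predictive_cdf()` simulates datasets from posterior draws at
the observed per-cell trial counts and summarizes defective CDFs —
RT quantiles scaled by response proportion, separately for correct and
error responses — with a 95% envelope across draws; cells with no
error responses are flagged undefined rather than imputed.

## The synthetic study

The generator emulates the design's generative structure rather than
its pixel-level stimuli:

* **Clock.** Reproductions follow a pacemaker-accumulator account:
  `reproduction = target × bias / rate_ratio × LogNormal noise` with a
  coefficient of variation `cv`.  `rate_ratio` is the current pacemaker
  rate over the rate at learning, fixed at 1 in Baseline cells; the
  default Warm-End value 1.10 produces ~9% underproduction, with 1.03
  at Warm-Begin.  `bias = 0.95` encodes the general underproduction
  tendency this task shows even at baseline, and `cv = 0.10` is a
  conventional scalar-timing Weber fraction.
* **Choice.** Choice trials are simulated from the LBA itself (start
  points and drifts drawn per trial), not from a frame-level model of
  the flicker stimulus: the analysis fits the LBA to behavior, so the
  generator matches that level of description.  Flicker stimulus
  streams (Bernoulli rates 0.7 target / 0.3 foil, side randomized per
  trial) are generated for task fidelity and testability but do not
  drive the simulated decisions.  Trials whose drift draws are all
  negative are re-drawn — the conditional-on-response convention that
  matches the un-normalized likelihood — and the re-draw rate is
  recorded (order $10^{-4}$ at default parameters).  Deadline misses
  are flagged and retained.
* **Group truth.** LBA group means (v 3.2, Δv 1.8, s_error 1.0, A 0.6,
  B 0.9, t0 0.18 s) give RTs of a few hundred milliseconds against the
  1 s deadline at ~85–90% accuracy, the regime this task design aims
  for.  Each participant draws one deviation per base parameter, shared
  across cells, so the shared-parameter assumption of the fitted models
  is true in the generator.
* **Coupling.** Each participant's Warm-End speed-up is drawn around
  the group rate ratio (SD 0.04); their threshold gap in Warm in-tub
  cells drops by `coupling × (rate_ratio − 1)` plus noise
  (defaults 2.0 and 0.05).  A faster clock therefore predicts both more
  underproduction and a lower threshold, which is the cross-task
  correlation structure the behavioral pipeline is meant to recover.
* **Determinism.** One master seed; per-participant, per-cell, per-task
  child streams are derived from it by a fixed integer hash, so any
  subset of the study regenerates identically.

What the generator does **not** emulate: within-trial evidence dynamics
of the flicker stream, physiological trajectories (core temperature,
heart rate), session-order or fatigue effects, and lapses or
fast guesses beyond what the LBA itself produces.  Passing tests
therefore show that the pipeline recovers the structure this generator
builds in; they cannot show that real data meet the model's
assumptions.

## Preprocessing

The order is fixed: validate → exclude choice RTs faster than 200 ms
(strict inequality, so exactly 0.2 s is retained) → add natural-log
RTs.  Baseline-relative z-scores use each session's own out-of-tub
Baseline mean and SD; accuracy, being nominal, is instead summarized
with the session Baseline accuracy as a covariate column and a
difference score.  Deadline-missed trials stay in the likelihood with
their observed RTs by default (the deadline gated feedback, not
responding); `drop_late = TRUE` provides the alternative.  Whether the
original analysis pooled the two sessions' baselines is not stated; the
per-session choice is used here because each visit has its own
out-of-tub measurement.

## Identifiability and what the recovery tests show

At desk scale (hundreds of trials per participant, 4–8 participants)
the LBA likelihood is nearly flat along a ridge trading the start-point
range $A$ against the threshold gap $B$ and non-decision time $t_0$:
refitting the same participant from different starts can move $A$ by
several tenths at a log-likelihood cost of 1–2 units.  A fully mixed
posterior is correspondingly wide along that ridge, and the group-level
2-posterior-SD recovery checks in the test suite pass or fail largely
with how completely the chain population spreads back out along the
ridge within the run length used.  This is why the overdispersed prior
initialization is the default, why the convergence criterion is the
sampler's headline property, and why drift-rate and $\Delta v$
hypermeans recover much more tightly than $A$ and $t_0$ — the same
asymmetry this model family shows on real data.

## Problem sizes used in tests and the acceptance script

Simulation-backed checks in the test suite use reduced problem sizes
chosen to exercise each property at meaningful power: Monte-Carlo
kernel oracles at $10^5$–$10^6$ draws; the truncated-normal sampler
validation at 10,000 retained samples; parameter recovery at 8
participants × 200 trials × 2 cells over 10 seeds with a shortened
schedule; model recovery and the end-to-end coupling analysis at 4–10
participants over 10 seeds.  The acceptance script runs the full
printed estimation schedule (1,000 burn-in, 5,000 sampling, thinning 5)
on 6 participants × 150 trials × 2 cells.  The methods, priors, and
sampler settings are identical across scales; only the problem sizes
differ.
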