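# Shared fixtures: parameter sets spanning the prior ranges, and small
# synthetic datasets built in code.

# Five LBA parameter sets spanning the participant-level prior ranges:
# easy/fast, hard/slow, high start-point variability, strong urgency,
# near-threshold drift.
fixture_param_sets <- function() {
  list(
    easy    = lba_params(A = 0.5, B = 0.5, v_correct = 3, delta_v = 2,
                         s_error = 1, t0 = 0.2),
    hard    = lba_params(A = 0.8, B = 1.5, v_correct = 2, delta_v = 0.5,
                         s_error = 1.2, t0 = 0.3),
    wide_A  = lba_params(A = 2.0, B = 0.3, v_correct = 4, delta_v = 3,
                         s_error = 0.8, t0 = 0.1),
    urgent  = lba_params(A = 0.4, B = 1.0, v_correct = 2.5, delta_v = 1.5,
                         s_error = 1, t0 = 0.15, urgency = 1.2),
    shallow = lba_params(A = 0.3, B = 2.5, v_correct = 1.2, delta_v = 0.8,
                         s_error = 0.5, t0 = 0.4)
  )
}

# Monte-Carlo oracle for the single-accumulator crossing CDF: start
# ~ U[0, A], drift ~ N(v, s), crossed by t iff drift > 0 and
# (b - start) / drift <= t.  Returns estimate and its standard error.
mc_accumulator_cdf <- function(t, A, b, v, s, n = 1e5, seed = 1) {
  set.seed(seed)
  start <- stats::runif(n, 0, A)
  drift <- stats::rnorm(n, v, s)
  hit <- drift > 0 & (b - start) / drift <= t
  list(est = mean(hit), se = stats::sd(hit) / sqrt(n))
}

# Monte-Carlo oracle for two-accumulator defective probabilities: fraction
# of trials where the given response wins and its RT is <= rt.
mc_defective_cdf <- function(rt, response, params, n = 1e5, seed = 1) {
  set.seed(seed)
  v <- c(params$v_correct + params$urgency,
         params$v_error + params$urgency)
  s <- c(params$s_correct, params$s_error)
  st_t <- stats::runif(n, 0, params$A)
  st_f <- stats::runif(n, 0, params$A)
  d_t <- stats::rnorm(n, v[1], s[1])
  d_f <- stats::rnorm(n, v[2], s[2])
  tt <- ifelse(d_t > 0, (params$b - st_t) / d_t, Inf)
  tf <- ifelse(d_f > 0, (params$b - st_f) / d_f, Inf)
  win_t <- is.finite(tt) & tt <= tf
  win_f <- is.finite(tf) & tf < tt
  win <- if (response == "target") win_t else win_f
  hit <- win & (params$t0 + pmin(tt, tf)) <= rt
  list(est = mean(hit), se = stats::sd(hit) / sqrt(n))
}

# A small two-cell study with its preprocessed choice trials.
fixture_small_study <- function(n_participants = 3, n_trials = 30,
                                seed = 42,
                                cells = c("Warm:Baseline", "Warm:End")) {
  st <- generate_study(n_participants = n_participants,
                       n_trials_per_cell = n_trials, seed = seed,
                       cells = cells)
  pp <- preprocess_trials(as_trial_table(st))
  list(study = st, trials = pp$trials,
       choice = pp$trials[pp$trials$task == "choice", ],
       manifest = pp$manifest)
}

# Closed-form mean and SD of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  m <- mu + sigma * (stats::dnorm(al) - stats::dnorm(be)) / Z
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                    ((stats::dnorm(al) - stats::dnorm(be)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}
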