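#!/usr/bin/env Rscript

# Step 3 — fit the three hierarchical LBA variants.
#
# The variants differ in what may change across design cells: the drift
# rate (stimulus evidence + urgency, not separately identifiable), the
# threshold gap B, or both; A, s_error, t0 and delta_v are always shared.
# Each is fitted by DE-MCMC with the standard scheme (D = 3 x parameter
# count chains, crossover weight 2.38/sqrt(D), migration during burn-in).
# To keep this driver interactive-scale it fits the two Warm-session
# cells where the effect of interest lives, at a reduced schedule; the
# full printed schedule is what scripts/acceptance.R runs.
#
# Writes one results/fits/<variant>/ directory per variant (posterior CSV
# + JSON manifest).

suppressPackageStartupMessages(library(thermolba))

trials <- read_trials("results/clean/trials_clean.csv")
cells <- c("Warm:Baseline", "Warm:End")
choice <- trials[trials$task == "choice" & trials$cell %in% cells, ]

for (variant in c("rate_only", "threshold_only", "both")) {
  model <- build_model(variant, cells)
  message(sprintf("Fitting %s: %d parameters, D = %d chains ...",
                  variant, model$n_params, model$D))
  t0 <- Sys.time()
  fit <- run_sampler(choice, model,
                     config = sampler_config(n_burn = 400, n_sample = 800,
                                             thin = 5, seed = 42))
  message(sprintf("  done in %.1f min; participant acceptance %.3f",
                  as.numeric(Sys.time() - t0, units = "mins"),
                  fit$acceptance$participant))
  conv <- hier_psrf(fit)
  message(sprintf("  median multivariate PSRF %.3f (threshold %.2f)",
                  conv$median_mpsrf, conv$threshold))
  write_fit(fit, file.path("results/fits", variant))
}
message("Fits written under results/fits/")
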