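#!/usr/bin/env Rscript

# Step 5 — baseline-relative behavior and the cross-task correlations.
#
# Expresses reproductions and log RTs as z-scores against each session's
# own out-of-tub Baseline, computes per-cell accuracy with the Baseline
# accuracy as covariate, extracts per-participant posterior-mean threshold
# changes from the winning fit, and correlates the timing change with the
# threshold change (the coupling the generator builds in: a faster clock
# goes with more underproduction and a lower threshold, so the correlation
# is expected positive).  Writes results/correlations/*.csv.

suppressPackageStartupMessages(library(thermolba))

trials <- read_trials("results/clean/trials_clean.csv")
dir.create("results/correlations", recursive = TRUE, showWarnings = FALSE)

z_rep <- baseline_zscore(trials, "reproduction_s")
z_rt <- baseline_zscore(log_transform_rts(trials), "log_rt_s")
acc <- accuracy_measures(trials)
write.csv(z_rep, "results/correlations/zscores_reproduction.csv",
          row.names = FALSE)
write.csv(z_rt, "results/correlations/zscores_logrt.csv", row.names = FALSE)
write.csv(acc, "results/correlations/accuracy_measures.csv",
          row.names = FALSE)

message("Mean reproduction z-score by condition x moment:")
print(round(tapply(z_rep$value, list(z_rep$condition, z_rep$moment), mean), 3))

# timing change vs accuracy change across tasks
acc_chg <- data.frame(participant_id = acc$participant_id,
                      condition = acc$condition, moment = acc$moment,
                      value = acc$accuracy_change)
r_beh <- correlate_changes(z_rep, acc_chg)
write.csv(r_beh, "results/correlations/timing_vs_accuracy.csv",
          row.names = FALSE)
message("Correlation of reproduction change with accuracy change:")
print(r_beh)

# timing change vs fitted threshold change (Warm session)
fit <- read_fit("results/fits/threshold_only")
b_chg <- parameter_change(fit, "B", "Warm:Baseline", "Warm:End")
z_end <- z_rep[z_rep$condition == "Warm" & z_rep$moment == "End", ]
r_par <- correlate_changes(z_end, b_chg)
write.csv(r_par, "results/correlations/timing_vs_threshold.csv",
          row.names = FALSE)
message("Correlation of reproduction change with fitted threshold change (Warm):")
print(r_par)
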