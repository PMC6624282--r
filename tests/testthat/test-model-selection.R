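# Deviance summaries, BPIC comparison, posterior-predictive defective CDFs.

# One small fitted posterior shared across the file.
local({
  cells <<- c("Warm:Baseline", "Warm:End")
  fx <- fixture_small_study(n_participants = 3, n_trials = 40, seed = 77,
                            cells = cells)
  ms_choice <<- fx$choice
  ms_model <<- build_model("threshold_only", cells)
  ms_fit <<- run_sampler(ms_choice, ms_model,
                         config = sampler_config(n_burn = 150,
                                                 n_sample = 250, thin = 5,
                                                 seed = 31))
})

test_that("deviance summaries: stored log likelihoods and the loop oracle", {
  s <- deviance_summaries(ms_fit, ms_choice)
  # recompute Dbar naively from 50 retained samples
  d <- dim(ms_fit$theta)
  idx <- expand.grid(r = seq_len(d[1]), i = seq_len(d[2]))
  take <- idx[seq(1, nrow(idx), length.out = 50), ]
  devs <- apply(take, 1, function(k) {
    r <- k[["r"]]; i <- k[["i"]]
    theta_all <- lapply(seq_len(d[4]), function(j) {
      th <- ms_fit$theta[r, i, , j]; names(th) <- ms_model$layout$name; th })
    names(theta_all) <- ms_fit$participants
    -2 * dataset_loglik(ms_choice, theta_all, ms_model)
  })
  stored <- -2 * apply(ms_fit$loglik, c(1, 2), sum)
  naive <- stored[cbind(take$r, take$i)]
  expect_equal(unname(devs), unname(naive), tolerance = 1e-9)
  expect_equal(s$Dbar, mean(stored), tolerance = 1e-12)
  # BPIC algebraic identity
  expect_equal(s$BPIC, s$Dbar + 2 * s$pD, tolerance = 1e-12)
  expect_error(deviance_summaries(ms_fit, ms_choice[-1, ]), "do not match")
})

test_that("a degenerate (constant) posterior has pD = 0 and BPIC = Dbar", {
  const <- ms_fit
  d <- dim(const$theta)
  for (r in seq_len(d[1])) for (i in seq_len(d[2])) {
    const$theta[r, i, , ] <- const$theta[1, 1, , ]
    const$phi_mean[r, i, ] <- const$phi_mean[1, 1, ]
    const$phi_sd[r, i, ] <- const$phi_sd[1, 1, ]
    const$loglik[r, i, ] <- const$loglik[1, 1, ]
  }
  s <- deviance_summaries(const, ms_choice)
  expect_equal(s$pD, 0, tolerance = 1e-6)
  expect_equal(s$BPIC, s$Dbar, tolerance = 1e-6)
  expect_false(s$pD_negative)
})

test_that("the minimum-deviance pD variant is available", {
  s_mean <- deviance_summaries(ms_fit, ms_choice, pd_variant = "mean")
  s_min <- deviance_summaries(ms_fit, ms_choice, pd_variant = "min")
  expect_gte(s_min$pD, 0)
  expect_false(identical(s_mean$pD, s_min$pD))
})

test_that("model comparison: ties, ranking, and the same-data guard", {
  tie <- compare_models(list(a = ms_fit, b = ms_fit), ms_choice)
  expect_equal(tie$delta_BPIC, c(0, 0))
  expect_true(all(tie$tied_best))
  # different data -> error
  other <- fixture_small_study(n_participants = 3, n_trials = 40,
                               seed = 78, cells = cells)
  fit2 <- run_sampler(other$choice, ms_model,
                      config = sampler_config(n_burn = 60, n_sample = 60,
                                              thin = 5, seed = 8))
  expect_error(compare_models(list(ms_fit, fit2), ms_choice),
               "identical datasets")
  # ranking is invariant to a common shift of all log likelihoods
  shifted <- ms_fit
  shifted$loglik <- shifted$loglik + 3.7
  fitb <- run_sampler(ms_choice, ms_model,
                      config = sampler_config(n_burn = 60, n_sample = 100,
                                              thin = 5, seed = 12))
  fitb_shift <- fitb
  fitb_shift$loglik <- fitb_shift$loglik + 3.7
  base <- compare_models(list(x = ms_fit, y = fitb), ms_choice)
  shift <- compare_models(list(x = shifted, y = fitb_shift), ms_choice)
  expect_equal(base$variant[base$rank == 1], shift$variant[shift$rank == 1])
  expect_equal(base$delta_BPIC, shift$delta_BPIC, tolerance = 1e-9)
})

test_that("posterior predictive CDF: mass accounting and envelope coverage", {
  ppc <- posterior_predictive_cdf(ms_fit, ms_choice, n_pp = 100, seed = 5)
  expect_equal(ppc$quantiles, c(0.1, 0.3, 0.5, 0.7, 0.9))
  # correct + error proportions sum to 1 within each cell
  for (src in list(ppc$observed, ppc$predicted)) {
    for (cl in unique(src$cell)) {
      props <- unique(src$proportion[src$cell == cl])
      expect_equal(sum(props), 1, tolerance = 1e-9)
    }
  }
  # defective scaling: cumulative proportion never exceeds the response mass
  expect_true(all(ppc$observed$cum_prop <= ppc$observed$proportion + 1e-12))
  # self-consistency: quantiles of data simulated from the posterior's own
  # mean parameters fall inside the 95% predictive envelope for most
  # (cell, quantile) pairs
  pm <- participant_posterior_means(ms_fit)
  counts <- table(ms_choice$participant_id, ms_choice$cell)
  sim <- list()
  for (id in rownames(counts)) {
    for (cl in colnames(counts)) {
      p <- cell_params(pm[id, ], ms_model, cl)
      sim[[length(sim) + 1L]] <- simulate_choices(
        p, n = counts[id, cl], seed = thermolba:::derive_seed(123, id, cl),
        cell = cl, participant_id = id)
    }
  }
  sim <- do.call(rbind, sim)
  checks <- 0L; inside <- 0L
  for (cl in unique(ppc$predicted$cell)) {
    for (type in c("correct", "error")) {
      keep <- if (type == "correct") sim$correct else !sim$correct
      rts <- sim$rt_s[sim$cell == cl & keep]
      if (length(rts) < 5) next
      q <- quantile(rts, ppc$quantiles, names = FALSE)
      env <- ppc$predicted[ppc$predicted$cell == cl &
                             ppc$predicted$response_type == type, ]
      env <- env[order(env$quantile), ]
      checks <- checks + length(q)
      inside <- inside + sum(q >= env$rt_lo & q <= env$rt_hi)
    }
  }
  expect_gte(inside / checks, 0.9)
})

test_that("cells with no error responses are flagged, not imputed", {
  # force an all-correct cell by overwriting responses
  ch <- ms_choice
  sel <- ch$cell == cells[1]
  ch$correct[sel] <- 1L
  ch$response[sel] <- "target"
  fit <- run_sampler(ch, ms_model,
                     config = sampler_config(n_burn = 60, n_sample = 60,
                                             thin = 5, seed = 9))
  ppc <- posterior_predictive_cdf(fit, ch, n_pp = 10, seed = 2)
  err <- ppc$observed[ppc$observed$cell == cells[1] &
                        ppc$observed$response_type == "error", ]
  expect_true(all(!err$defined))
  expect_true(all(is.na(err$rt)))
})

test_that("parameter changes require the parameter to vary across cells", {
  pc <- parameter_change(ms_fit, "B", cells[1], cells[2])
  pm <- participant_posterior_means(ms_fit)
  expect_equal(pc$value,
               unname(pm[, paste("B", cells[2], sep = "|")] -
                        pm[, paste("B", cells[1], sep = "|")]))
  expect_equal(pc$condition, rep("Warm", 3))
  expect_equal(pc$moment, rep("End", 3))
  expect_error(parameter_change(ms_fit, "v_correct", cells[1], cells[2]),
               "not free")
})

test_that("fit serialization writes the full posterior and manifest", {
  dir <- withr::local_tempdir()
  paths <- write_fit(ms_fit, dir)
  post <- read.csv(paths$posterior, stringsAsFactors = FALSE)
  d <- dim(ms_fit$theta)
  expect_equal(nrow(post),
               d[1] * d[2] * d[3] * d[4] + 2 * d[1] * d[2] * d[3] +
                 d[1] * d[2] * d[4])
  expect_setequal(unique(post$level),
                  c("participant", "group_mean", "group_sd", "loglik"))
  one <- post[post$level == "participant" & post$chain == 2 &
                post$iteration == 3 & post$participant == ms_fit$participants[1] &
                post$parameter == "A", ]
  expect_equal(one$value, ms_fit$theta[3, 2, "A", 1])
  man <- jsonlite::read_json(paths$manifest)
  expect_equal(man$variant, "threshold_only")
  expect_equal(man$D, ms_model$D)
  expect_equal(man$data_hash, ms_fit$data_hash)
  # round trip: deviance summaries recomputable from the serialized fit
  back <- read_fit(dir)
  expect_equal(back$theta, ms_fit$theta)
  expect_equal(back$loglik, ms_fit$loglik)
  s1 <- deviance_summaries(ms_fit, ms_choice)
  s2 <- deviance_summaries(back, ms_choice)
  expect_equal(s2$BPIC, s1$BPIC, tolerance = 1e-9)
})
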