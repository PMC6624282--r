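# Model selection: deviance summaries, BPIC, ranking across the three
# variants, and posterior-predictive defective CDF summaries.

#' Posterior means of participant-level parameters
#'
#' @param fit A [run_sampler()] result.
#' @return Matrix participants x parameters of posterior means (pooled over
#'   retained iterations and chains).
#' @export
participant_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  d <- dim(fit$theta)
  out <- matrix(NA_real_, d[4], d[3],
                dimnames = list(fit$participants, dimnames(fit$theta)[[3]]))
  for (j in seq_len(d[4]))
    out[j, ] <- apply(fit$theta[, , , j, drop = FALSE], 3, mean)
  out
}

#' Posterior means of group-level parameters
#'
#' @param fit A [run_sampler()] result.
#' @return List with named vectors `mean` (hypermeans) and `sd` (hyperSDs),
#'   plus `mean_sd` / `sd_sd`, the posterior SDs of each.
#' @export
group_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  list(mean = apply(fit$phi_mean, 3, mean),
       sd = apply(fit$phi_sd, 3, mean),
       mean_sd = apply(fit$phi_mean, 3, stats::sd),
       sd_sd = apply(fit$phi_sd, 3, stats::sd))
}

#' Per-participant posterior-mean change of a parameter between two cells
#'
#' Convenience for the cross-task correlation analyses: the posterior mean
#' of `base` in `cell_to` minus in `cell_from`, per participant, shaped for
#' [correlate_changes()].
#'
#' @param fit A [run_sampler()] result.
#' @param base Base parameter name (must be free across cells in the fitted
#'   variant).
#' @param cell_from,cell_to Cell labels.
#' @return Data frame: `participant_id`, `condition`, `moment` (of
#'   `cell_to`), `value`.
#' @export
parameter_change <- function(fit, base, cell_from, cell_to) {
  pm <- participant_posterior_means(fit)
  n_from <- paste(base, cell_from, sep = "|")
  n_to <- paste(base, cell_to, sep = "|")
  if (!all(c(n_from, n_to) %in% colnames(pm)))
    stop(base, " is not free across these cells in variant ",
         fit$model$variant)
  parts <- strsplit(cell_to, ":")[[1]]
  data.frame(participant_id = rownames(pm),
             condition = parts[1], moment = parts[2],
             value = pm[, n_to] - pm[, n_from],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deviance summaries of a hierarchical fit
#'
#' Mean posterior deviance `Dbar` (from the per-sample log-likelihoods
#' stored during fitting), deviance at the posterior mean `Dhat`, and the
#' effective number of parameters `pD = Dbar - Dhat` (default) or the
#' minimum-deviance variant `pD = Dbar - min(D)`.
#'
#' @param fit A [run_sampler()] result.
#' @param trials The preprocessed choice trials the model was fitted to
#'   (needed to evaluate the deviance at the posterior mean).
#' @param pd_variant `"mean"` (deviance at posterior mean) or `"min"`
#'   (minimum posterior deviance).
#' @return List with `Dbar`, `Dhat`, `pD`, `BPIC`, `pd_variant`,
#'   `pD_negative` flag.
#' @export
deviance_summaries <- function(fit, trials, pd_variant = c("mean", "min")) {
  stopifnot(inherits(fit, "hier_fit"))
  pd_variant <- match.arg(pd_variant)
  if (!identical(hash_trials(trials), fit$data_hash))
    stop("trials do not match the data this model was fitted to")
  total_ll <- apply(fit$loglik, c(1, 2), sum)   # iteration x chain
  Dbar <- mean(-2 * total_ll)
  pdat <- participant_data(trials, fit$model)
  pm <- participant_posterior_means(fit)
  ll_hat <- sum(vapply(seq_along(pdat), function(j)
    participant_loglik_fast(pm[names(pdat)[j], ], pdat[[j]], fit$model),
    numeric(1)))
  Dhat <- -2 * ll_hat
  pD <- switch(pd_variant,
               mean = Dbar - Dhat,
               min = Dbar - min(-2 * total_ll))
  list(Dbar = Dbar, Dhat = Dhat, pD = pD, BPIC = Dbar + 2 * pD,
       pd_variant = pd_variant,
       pD_negative = pD < -sqrt(.Machine$double.eps))
}

#' Compare model variants by BPIC
#'
#' All fits must be on identical preprocessed data (enforced via the stored
#' data hash).  Models are ranked by BPIC ascending; the best model has
#' `delta_BPIC = 0`, and exact ties are reported.
#'
#' @param fits Named list of [run_sampler()] results (names = variant
#'   labels; defaults to each fit's variant).
#' @param trials The shared preprocessed choice trials.
#' @param pd_variant Passed to [deviance_summaries()].
#' @return Data frame of class `model_comparison`: `variant`, `Dbar`,
#'   `Dhat`, `pD`, `BPIC`, `delta_BPIC`, `rank`, `tied_best`.
#' @export
compare_models <- function(fits, trials, pd_variant = "mean") {
  stopifnot(length(fits) >= 2)
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  n_tr <- vapply(fits, function(f) f$n_trials, numeric(1))
  if (length(unique(hashes)) != 1L || length(unique(n_tr)) != 1L)
    stop("fits were not run on identical datasets")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model$variant, character(1))
  rows <- lapply(names(fits), function(nm) {
    s <- deviance_summaries(fits[[nm]], trials, pd_variant)
    data.frame(variant = nm, Dbar = s$Dbar, Dhat = s$Dhat, pD = s$pD,
               BPIC = s$BPIC, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$delta_BPIC <- tab$BPIC - min(tab$BPIC)
  tab$rank <- rank(tab$BPIC, ties.method = "min")
  tab$tied_best <- tab$delta_BPIC == 0
  tab <- tab[order(tab$BPIC), ]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Posterior-predictive defective CDF summary
#'
#' Simulates datasets from posterior draws (matching the observed trial
#' counts per participant and cell), pools trials within each design cell,
#' and summarizes the defective CDF: for each cell and response correctness,
#' the RT quantiles of that response's distribution together with the
#' response proportion, so `cum_prop = quantile * proportion` traces the
#' defective curve.  Observed data are summarized identically.  Cells with
#' no error (or no correct) responses get undefined quantiles, flagged, not
#' imputed.
#'
#' @param fit A [run_sampler()] result.
#' @param trials The fitted choice trials.
#' @param n_pp Number of posterior draws to simulate (default 100).
#' @param quantiles Quantile set (default 0.1, 0.3, 0.5, 0.7, 0.9).
#' @param seed Seed for the predictive simulations.
#' @return List of class `ppc_cdf` with data frames `observed` (`cell`,
#'   `response_type`, `proportion`, `quantile`, `rt`, `cum_prop`,
#'   `defined`) and `predicted` (the same columns for the across-draw mean
#'   plus `rt_lo` / `rt_hi`, the 2.5% / 97.5% envelope across draws).
#' @export
posterior_predictive_cdf <- function(fit, trials, n_pp = 100,
                                     quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                     seed = 1) {
  stopifnot(inherits(fit, "hier_fit"))
  if (!identical(hash_trials(trials), fit$data_hash))
    stop("trials do not match the data this model was fitted to")
  model <- fit$model
  d <- dim(fit$theta)
  set.seed(seed)
  draw_iter <- sample.int(d[1], n_pp, replace = TRUE)
  draw_chain <- sample.int(d[2], n_pp, replace = TRUE)
  counts <- table(trials$participant_id, trials$cell)
  summarize <- function(df) {
    rows <- list()
    for (cl in model$cells) {
      sub <- df[df$cell == cl, ]
      n_cell <- nrow(sub)
      for (type in c("correct", "error")) {
        keep <- if (type == "correct") as.logical(sub$correct)
                else !as.logical(sub$correct)
        rts <- sub$rt_s[keep]
        prop <- if (n_cell) sum(keep) / n_cell else NA_real_
        if (length(rts) >= 1) {
          q <- stats::quantile(rts, quantiles, names = FALSE, type = 7)
          rows[[length(rows) + 1L]] <- data.frame(
            cell = cl, response_type = type, proportion = prop,
            quantile = quantiles, rt = q, cum_prop = quantiles * prop,
            defined = TRUE, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            cell = cl, response_type = type, proportion = prop,
            quantile = quantiles, rt = NA_real_,
            cum_prop = quantiles * prop, defined = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  ch <- trials[!is.na(trials$rt_s), ]
  observed <- summarize(ch)
  pred_draws <- vector("list", n_pp)
  for (k in seq_len(n_pp)) {
    sim <- list()
    for (j in seq_along(fit$participants)) {
      id <- fit$participants[j]
      theta <- fit$theta[draw_iter[k], draw_chain[k], , j]
      names(theta) <- dimnames(fit$theta)[[3]]
      for (cl in model$cells) {
        n_jc <- if (id %in% rownames(counts) && cl %in% colnames(counts))
          counts[id, cl] else 0L
        if (n_jc == 0L) next
        p <- cell_params(theta, model, cl)
        sim[[length(sim) + 1L]] <- simulate_choices(
          p, n = n_jc, deadline_s = 1.0,
          seed = derive_seed(seed, "ppc", k, id, cl),
          cell = cl, participant_id = id)
      }
    }
    s <- summarize(do.call(rbind, sim))
    s$draw <- k
    pred_draws[[k]] <- s
  }
  allp <- do.call(rbind, pred_draws)
  keycols <- c("cell", "response_type", "quantile")
  key <- interaction(allp[keycols], drop = TRUE)
  agg <- function(v, f) tapply(v, key, f)
  first <- !duplicated(key)
  predicted <- allp[first, c(keycols, "proportion")]
  k1 <- key[first]
  predicted$proportion <- as.numeric(agg(allp$proportion, function(x)
    mean(x, na.rm = TRUE))[k1])
  predicted$rt <- as.numeric(agg(allp$rt, function(x)
    mean(x, na.rm = TRUE))[k1])
  predicted$rt_lo <- as.numeric(agg(allp$rt, function(x)
    if (all(is.na(x))) NA_real_
    else stats::quantile(x, 0.025, na.rm = TRUE))[k1])
  predicted$rt_hi <- as.numeric(agg(allp$rt, function(x)
    if (all(is.na(x))) NA_real_
    else stats::quantile(x, 0.975, na.rm = TRUE))[k1])
  predicted$cum_prop <- predicted$quantile * predicted$proportion
  predicted$defined <- as.logical(agg(allp$defined, function(x)
    mean(x) > 0.5)[k1])
  rownames(predicted) <- NULL
  structure(list(observed = observed, predicted = predicted,
                 n_pp = n_pp, quantiles = quantiles),
            class = "ppc_cdf")
}
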