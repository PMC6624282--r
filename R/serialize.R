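# Serialization: synthetic studies to trial CSV + ground-truth sidecar,
# posterior fits to a long-format CSV + JSON run manifest.

#' Write a synthetic study to disk
#'
#' Writes the trial table in the CSV dialect of [write_trials()] and a JSON
#' sidecar holding every generative parameter and the master seed, so any
#' downstream result can be traced to its ground truth.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`trials`, `truth`).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trial_path <- file.path(dir, "trials.csv")
  write_trials(as_trial_table(study), trial_path,
               provenance = c(generator = "thermolba::generate_study",
                              seed = as.character(study$ground_truth$seed)))
  gt <- study$ground_truth
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    seed = gt$seed, cells = gt$cells,
    n_participants = gt$n_participants,
    n_trials_per_cell = gt$n_trials_per_cell,
    target_s = gt$target_s, deadline_s = gt$deadline_s,
    clock = list(rate_ratio = as.list(gt$truth$clock$rate_ratio),
                 bias = gt$truth$clock$bias, cv = gt$truth$clock$cv),
    coupling = gt$truth$coupling,
    coupling_noise_sd = gt$truth$coupling_noise_sd,
    rate_ratio_sd = gt$truth$rate_ratio_sd,
    group_mean = as.data.frame(gt$truth$group_mean),
    group_sd = as.data.frame(gt$truth$group_sd),
    participants = gt$participants),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(trials = trial_path, truth = truth_path))
}

#' Write a hierarchical fit to disk
#'
#' Long-format posterior CSV with columns `level` (participant/group_mean/
#' group_sd), `participant`, `parameter`, `cell`, `chain`, `iteration`,
#' `value`, plus a JSON run manifest (model layout, sampler configuration,
#' seed, acceptance rates, PSRF table, data hash).
#'
#' @param fit A [run_sampler()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written (`posterior`, `manifest`).
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "hier_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(fit$theta)
  layout <- fit$model$layout
  grid_p <- expand.grid(iteration = seq_len(d[1]), chain = seq_len(d[2]),
                        parameter = layout$name,
                        participant = fit$participants,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid_p$level <- "participant"
  grid_p$cell <- layout$cell[match(grid_p$parameter, layout$name)]
  grid_p$value <- as.vector(fit$theta)
  grid_g <- expand.grid(iteration = seq_len(d[1]), chain = seq_len(d[2]),
                        parameter = layout$name,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid_g$participant <- NA_character_
  grid_g$cell <- layout$cell[match(grid_g$parameter, layout$name)]
  gm <- grid_g; gm$level <- "group_mean"; gm$value <- as.vector(fit$phi_mean)
  gs <- grid_g; gs$level <- "group_sd"; gs$value <- as.vector(fit$phi_sd)
  # per-sample data log likelihoods, so deviance summaries are
  # recomputable from the serialized posterior alone
  grid_l <- expand.grid(iteration = seq_len(d[1]), chain = seq_len(d[2]),
                        participant = fit$participants,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid_l$level <- "loglik"
  grid_l$parameter <- NA_character_
  grid_l$cell <- NA_character_
  grid_l$value <- as.vector(fit$loglik)
  cols <- c("level", "participant", "parameter", "cell", "chain",
            "iteration", "value")
  post <- rbind(grid_p[cols], gm[cols], gs[cols], grid_l[cols])
  post_path <- file.path(dir, "posterior.csv")
  utils::write.csv(post, post_path, row.names = FALSE, na = "NA")
  conv <- hier_psrf(fit)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    variant = fit$model$variant,
    cells = fit$model$cells,
    layout = layout,
    n_params = fit$model$n_params,
    D = fit$model$D,
    config = unclass(fit$config),
    gamma_participant = fit$gamma_participant,
    acceptance = fit$acceptance[c("participant", "group",
                                  "migration_events")],
    psrf = list(per_participant = as.list(conv$per_participant),
                median_mpsrf = conv$median_mpsrf,
                group_mpsrf = conv$group_mpsrf),
    data_hash = fit$data_hash,
    n_trials = fit$n_trials),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(posterior = post_path, manifest = manifest_path))
}

#' Read a serialized hierarchical fit
#'
#' Reconstructs a `hier_fit` object (posterior arrays, per-sample log
#' likelihoods, model layout, configuration, data hash) from a directory
#' written by [write_fit()].  Acceptance-rate details that are not
#' serialized are restored from the manifest summary.
#'
#' @param dir Directory containing `posterior.csv` and `manifest.json`.
#' @return A `hier_fit` object.
#' @export
read_fit <- function(dir) {
  post <- utils::read.csv(file.path(dir, "posterior.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(participant = "character",
                                         parameter = "character"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  model <- build_model(man$variant, man$cells)
  pnames <- model$layout$name
  parts <- sort(unique(post$participant[post$level == "participant"]))
  n_ret <- max(post$iteration); D <- max(post$chain)
  pp <- post[post$level == "participant", ]
  theta <- array(NA_real_, c(n_ret, D, length(pnames), length(parts)),
                 dimnames = list(NULL, NULL, pnames, parts))
  theta[cbind(pp$iteration, pp$chain, match(pp$parameter, pnames),
              match(pp$participant, parts))] <- pp$value
  gm <- post[post$level == "group_mean", ]
  gs <- post[post$level == "group_sd", ]
  phi_mean <- array(NA_real_, c(n_ret, D, length(pnames)),
                    dimnames = list(NULL, NULL, pnames))
  phi_sd <- phi_mean
  phi_mean[cbind(gm$iteration, gm$chain, match(gm$parameter, pnames))] <-
    gm$value
  phi_sd[cbind(gs$iteration, gs$chain, match(gs$parameter, pnames))] <-
    gs$value
  llr <- post[post$level == "loglik", ]
  loglik <- array(NA_real_, c(n_ret, D, length(parts)),
                  dimnames = list(NULL, NULL, parts))
  loglik[cbind(llr$iteration, llr$chain, match(llr$participant, parts))] <-
    llr$value
  cfg <- do.call(sampler_config,
                 man$config[setdiff(names(man$config), NULL)])
  structure(list(theta = theta, phi_mean = phi_mean, phi_sd = phi_sd,
                 loglik = loglik,
                 acceptance = man$acceptance,
                 participants = parts, model = model,
                 priors = prior_spec(), config = cfg,
                 gamma_participant = man$gamma_participant,
                 data_hash = man$data_hash,
                 n_trials = man$n_trials),
            class = "hier_fit")
}
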