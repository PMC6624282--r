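# Differential-evolution MCMC for the hierarchical LBA model: crossover and
# migration moves with Metropolis-Hastings acceptance, blocked
# participant/group updates, burn-in + immediate thinning, convergence
# (Gelman-Rubin) and stuck-chain diagnostics.

#' Sampler configuration
#'
#' Defaults follow the estimation scheme used throughout: 1,000 burn-in
#' iterations, 5,000 sampling iterations with an immediate thinning factor
#' of 5, migration probability 0.05 during burn-in only, crossover weight
#' `2.38 / sqrt(D)` on the participant level (with `D` the chain count,
#' three times the participant-level parameter count) and drawn uniformly
#' from `[0.5, 1]` per move on the group level, and a uniform perturbation
#' on `[-0.001, 0.001]` added to every proposal coordinate.
#'
#' @param n_burn Burn-in iterations.
#' @param n_sample Post-burn-in sampling iterations.
#' @param thin Keep every `thin`-th sampling iteration.
#' @param migration_prob Per-block probability of a migration move instead
#'   of crossover, during burn-in only.
#' @param perturb Half-width of the uniform proposal perturbation.
#' @param seed Integer seed; fixes the whole run.
#' @param gamma_participant Optional override of the participant-level
#'   crossover weight (default `2.38 / sqrt(D)`, resolved at run time).
#' @param init_method Chain initialization: `"prior"` (default) draws every
#'   chain start from the participant-level priors, keeping the best of
#'   `init_best_of` finite-posterior draws, so starts are overdispersed;
#'   `"jitter"` locates a rough per-participant likelihood mode and
#'   scatters the chains tightly around it — faster to settle, but it can
#'   under-represent posterior spread along weakly identified directions,
#'   so it is not used for inference runs.
#' @param init_retries Maximum prior draws per chain when searching for a
#'   finite-posterior start.
#' @param init_best_of Number of finite-posterior prior draws from which the
#'   best is kept as the start (start points remain overdispersed draws from
#'   the participant-level priors; this only avoids hopeless corners).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_burn = 1000L, n_sample = 5000L, thin = 5L,
                           migration_prob = 0.05, perturb = 0.001,
                           seed = 1L, gamma_participant = NULL,
                           init_method = c("prior", "jitter"),
                           init_retries = 1000L, init_best_of = 20L) {
  stopifnot(n_burn >= 0, n_sample >= 1, thin >= 1,
            migration_prob >= 0, migration_prob <= 1, perturb >= 0,
            init_retries >= 1, init_best_of >= 1)
  init_method <- match.arg(init_method)
  structure(list(n_burn = as.integer(n_burn), n_sample = as.integer(n_sample),
                 thin = as.integer(thin), migration_prob = migration_prob,
                 perturb = perturb, seed = as.integer(seed),
                 gamma_participant = gamma_participant,
                 init_method = init_method,
                 init_retries = as.integer(init_retries),
                 init_best_of = as.integer(init_best_of)),
            class = "sampler_config")
}

#' One crossover update of a single chain
#'
#' Differential-evolution proposal: the chain's position plus `gamma` times
#' the difference between two other, distinct chains' positions, plus an
#' independent uniform perturbation on `[-perturb, perturb]` per
#' coordinate, accepted by Metropolis-Hastings on `log_post`.
#'
#' @param i Index of the chain to update.
#' @param pos Matrix of chain positions, chains x parameters (>= 3 rows).
#' @param lp Numeric vector of cached log posterior values per chain.
#' @param log_post Function mapping a parameter vector to a log posterior.
#' @param gamma Crossover weight.
#' @param perturb Perturbation half-width.
#' @return List with updated `pos`, `lp`, and logical `accepted`.
#' @export
crossover_update <- function(i, pos, lp, log_post, gamma, perturb = 0.001) {
  D <- nrow(pos)
  if (D < 3) stop("crossover needs at least 3 chains")
  donors <- sample(setdiff(seq_len(D), i), 2L)
  prop <- pos[i, ] + gamma * (pos[donors[1L], ] - pos[donors[2L], ]) +
    stats::runif(ncol(pos), -perturb, perturb)
  lp_prop <- log_post(prop)
  accepted <- is.finite(lp_prop) &&
    log(stats::runif(1)) < (lp_prop - lp[i])
  if (accepted) {
    pos[i, ] <- prop
    lp[i] <- lp_prop
  }
  list(pos = pos, lp = lp, accepted = accepted)
}

#' One migration sweep over a set of chains
#'
#' With probability `migration_prob` a random subset of chains (uniform size
#' from 1 to the chain count) forms a ring; each ring member proposes the
#' state the previous member held before the sweep, accepted chain by chain
#' with Metropolis-Hastings.  A single-chain ring proposes its own state (a
#' no-op).  Intended for burn-in only; the caller enforces the schedule.
#'
#' @param pos,lp As in [crossover_update()].
#' @param log_post Function mapping a parameter vector to a log posterior;
#'   only needed when per-chain posteriors differ, otherwise cached values
#'   are reused via `lp_for`.
#' @param migration_prob Probability that the sweep happens at all.
#' @param lp_for Optional function `(chain_index, param_vector) ->` log
#'   posterior, for targets that differ across chains (hierarchical blocks);
#'   defaults to `function(i, x) log_post(x)`.
#' @return List with updated `pos`, `lp`, number of accepted swaps
#'   `n_accept`, and whether the sweep ran (`migrated`).
#' @export
migration_update <- function(pos, lp, log_post, migration_prob = 0.05,
                             lp_for = NULL) {
  D <- nrow(pos)
  if (stats::runif(1) >= migration_prob)
    return(list(pos = pos, lp = lp, n_accept = 0L, migrated = FALSE))
  if (is.null(lp_for)) lp_for <- function(i, x) log_post(x)
  k <- sample.int(D, 1L)
  ring <- sample.int(D, k)
  old_pos <- pos[ring, , drop = FALSE]
  n_accept <- 0L
  for (m in seq_len(k)) {
    target <- ring[m]
    donor_row <- if (m == 1L) k else m - 1L
    prop <- old_pos[donor_row, ]
    lp_prop <- lp_for(target, prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < (lp_prop - lp[target])) {
      pos[target, ] <- prop
      lp[target] <- lp_prop
      n_accept <- n_accept + 1L
    }
  }
  list(pos = pos, lp = lp, n_accept = n_accept, migrated = TRUE)
}

#' DE-MCMC on a single unnormalized log target
#'
#' Non-hierarchical convenience sampler used for validating the move kernel
#' against targets with known moments, and as the building block pattern for
#' [run_sampler()].  Crossover with weight `2.38 / sqrt(D)` (overridable),
#' migration during burn-in, immediate thinning.
#'
#' @param log_target Function: parameter vector -> log density.
#' @param init Matrix of starting positions, chains x parameters.
#' @param config A [sampler_config()].
#' @param gamma Crossover weight; default `2.38 / sqrt(nrow(init))`.
#' @return List with `samples` (array: retained iteration x chain x
#'   parameter), `acceptance` (crossover acceptance rate), and `config`.
#' @export
demcmc_sample <- function(log_target, init, config = sampler_config(),
                          gamma = NULL) {
  pos <- as.matrix(init)
  D <- nrow(pos); P <- ncol(pos)
  if (D < 4) stop("need at least 4 chains")
  if (is.null(gamma)) gamma <- 2.38 / sqrt(D)
  set.seed(config$seed)
  lp <- apply(pos, 1, log_target)
  if (any(!is.finite(lp))) stop("initial positions must have finite log target")
  n_ret <- config$n_sample %/% config$thin
  samples <- array(NA_real_, c(n_ret, D, P))
  n_acc <- 0L; n_prop <- 0L; ret <- 0L
  for (it in seq_len(config$n_burn + config$n_sample)) {
    burn <- it <= config$n_burn
    if (burn) {
      mig <- migration_update(pos, lp, log_target, config$migration_prob)
      pos <- mig$pos; lp <- mig$lp
    }
    for (i in seq_len(D)) {
      up <- crossover_update(i, pos, lp, log_target, gamma, config$perturb)
      pos <- up$pos; lp <- up$lp
      n_acc <- n_acc + up$accepted; n_prop <- n_prop + 1L
    }
    if (!burn && (it - config$n_burn) %% config$thin == 0L) {
      ret <- ret + 1L
      samples[ret, , ] <- pos
    }
  }
  list(samples = samples, acceptance = n_acc / n_prop, config = config)
}

# Rough per-participant likelihood mode: best of a few prior draws refined
# by bounded quasi-Newton steps.  Used only to place chain starts.
participant_mode <- function(pd, lo, hi) {
  P <- length(lo)
  cands <- list(); lls <- numeric(0)
  for (k in seq_len(100)) {
    cand <- stats::runif(P, lo, hi)
    llc <- lba_loglik_chains(matrix(cand, 1L), pd$cellidx, pd$rt,
                             pd$correct)[1L]
    cands[[k]] <- cand; lls[k] <- llc
  }
  ord <- order(lls, decreasing = TRUE)
  best <- cands[[ord[1]]]; best_val <- -lls[ord[1]]
  neg_ll <- function(x)
    -lba_loglik_chains(matrix(x, 1L), pd$cellidx, pd$rt, pd$correct)[1L]
  for (s in ord[1:2]) {
    opt <- try(stats::optim(cands[[s]], neg_ll, method = "L-BFGS-B",
                            lower = lo + 1e-8, upper = hi - 1e-8,
                            control = list(maxit = 100)), silent = TRUE)
    if (!inherits(opt, "try-error") && is.finite(opt$value) &&
        opt$value < best_val) {
      best <- opt$par; best_val <- opt$value
    }
  }
  best
}

#' Fit the hierarchical LBA model by DE-MCMC
#'
#' Alternates blocked updates each iteration: every participant's parameter
#' vector is updated conditional on that participant's data and the chain's
#' group-level parameters, then the group-level parameters are updated
#' conditional on all participants' parameters, one (hypermean, hyperSD)
#' pair per participant-level parameter.  Proposals are differential-
#' evolution crossovers over the chain population (participant-level weight
#' `2.38 / sqrt(D)`, group-level weight drawn uniformly from `[0.5, 1]` per
#' move, perturbation `[-0.001, 0.001]`), applied chain by chain so accepted
#' moves are immediately available as donors.  During burn-in each block may
#' instead perform a migration sweep with probability 0.05.  Sampling
#' iterations are thinned immediately; only the retained buffer is kept.
#' The run is fully reproducible from the seed in `config`.
#'
#' @param trials Data frame of preprocessed choice trials (columns
#'   `participant_id`, `cell`, `rt_s`, `correct`); apply
#'   [filter_fast_rts()] first.
#' @param model An [build_model()] object covering every cell in `trials`.
#' @param priors A [prior_spec()] list.
#' @param config A [sampler_config()].
#' @return An object of class `hier_fit`: arrays `theta` (retained iteration
#'   x chain x parameter x participant), `phi_mean` / `phi_sd` (iteration x
#'   chain x parameter), `loglik` (iteration x chain x participant),
#'   acceptance-rate summaries, participant ids, model, config, and a hash
#'   of the fitted data.
#' @export
run_sampler <- function(trials, model, priors = prior_spec(),
                        config = sampler_config()) {
  stopifnot(inherits(model, "lba_model"), inherits(config, "sampler_config"))
  pdat <- participant_data(trials, model)
  J <- length(pdat); P <- model$n_params; D <- model$D
  if (D < 4) stop("chain count too small")
  gamma_p <- if (is.null(config$gamma_participant)) 2.38 / sqrt(D)
             else config$gamma_participant
  pb <- participant_bounds(model, priors)
  hb <- hypermean_bounds(model, priors)
  lo <- pb[, "lower"]; hi <- pb[, "upper"]
  hlo <- hb[, "lower"]; hhi <- hb[, "upper"]
  g_shape <- priors$hypersd_shape; g_rate <- priors$hypersd_rate
  set.seed(config$seed)

  # --- initialization -------------------------------------------------
  phi_mean <- matrix(NA_real_, D, P)
  phi_sd <- matrix(NA_real_, D, P)
  for (i in seq_len(D)) {
    phi_mean[i, ] <- stats::runif(P, hlo, hhi)
    phi_sd[i, ] <- stats::rgamma(P, shape = g_shape, rate = g_rate) + 0.01
  }
  # per-chain, per-parameter caches:
  #   lognorm  D x P: log truncation mass of the participant prior
  #   sd_term  D x P: Gamma log density of the hyperSD
  #   lpp      J x P x D: per-parameter participant log prior contributions
  lognorm <- t(vapply(seq_len(D), function(i)
    trunc_lognorm(phi_mean[i, ], phi_sd[i, ], lo, hi), numeric(P)))
  sd_term <- matrix(stats::dgamma(phi_sd, shape = g_shape, rate = g_rate,
                                  log = TRUE), D, P)
  theta <- array(NA_real_, c(D, P, J))
  ll <- matrix(NA_real_, J, D)   # data loglik, participant x chain
  lpp <- array(NA_real_, c(J, P, D))
  modes <- if (config$init_method == "jitter")
    lapply(pdat, participant_mode, lo = lo, hi = hi) else NULL
  if (config$init_method == "jitter") {
    # re-center the group-level starts on the spread of participant modes
    mode_mat <- do.call(rbind, modes)
    mcenter <- colMeans(mode_mat)
    mspread <- pmax(apply(mode_mat, 2, stats::sd), 0.1)
    for (i in seq_len(D)) {
      phi_mean[i, ] <- pmin(pmax(mcenter +
                                   stats::rnorm(P, 0, mspread), hlo), hhi)
      phi_sd[i, ] <- mspread * stats::runif(P, 0.5, 1.5)
    }
    lognorm <- t(vapply(seq_len(D), function(i)
      log(pmax(stats::pnorm(hi, phi_mean[i, ], phi_sd[i, ]) -
                 stats::pnorm(lo, phi_mean[i, ], phi_sd[i, ]), 1e-300)),
      numeric(P)))
    sd_term <- matrix(stats::dgamma(phi_sd, shape = g_shape, rate = g_rate,
                                    log = TRUE), D, P)
  }
  for (j in seq_len(J)) {
    jscale <- if (is.null(modes)) NULL
              else pmax(0.1 * pmin(abs(modes[[j]]), 2), 0.02)
    for (i in seq_len(D)) {
      best <- NULL; best_val <- -Inf; found <- 0L
      for (try in seq_len(config$init_retries)) {
        cand <- if (is.null(modes)) stats::runif(P, lo, hi)
                else pmin(pmax(modes[[j]] + stats::rnorm(P, 0, jscale),
                               lo + 1e-9), hi - 1e-9)
        ll_c <- lba_loglik_chains(matrix(cand, 1L), pdat[[j]]$cellidx,
                                  pdat[[j]]$rt, pdat[[j]]$correct)[1L]
        if (!is.finite(ll_c)) next
        contrib <- stats::dnorm(cand, phi_mean[i, ], phi_sd[i, ],
                                log = TRUE) - lognorm[i, ]
        if (any(!is.finite(contrib))) next
        found <- found + 1L
        if (ll_c + sum(contrib) > best_val) {
          best_val <- ll_c + sum(contrib)
          best <- list(cand, ll_c, contrib)
        }
        if (found >= config$init_best_of ||
            (!is.null(modes) && found >= 1L)) break
      }
      if (is.null(best))
        stop("no finite-posterior start found for participant ",
             names(pdat)[j], ", chain ", i,
             " after ", config$init_retries, " prior draws")
      theta[i, , j] <- best[[1]]
      ll[j, i] <- best[[2]]; lpp[j, , i] <- best[[3]]
    }
  }

  # --- storage --------------------------------------------------------
  n_ret <- config$n_sample %/% config$thin
  theta_store <- array(NA_real_, c(n_ret, D, P, J),
                       dimnames = list(NULL, NULL, model$layout$name,
                                       names(pdat)))
  phim_store <- array(NA_real_, c(n_ret, D, P),
                      dimnames = list(NULL, NULL, model$layout$name))
  phis_store <- phim_store
  ll_store <- array(NA_real_, c(n_ret, D, J),
                    dimnames = list(NULL, NULL, names(pdat)))
  acc_part <- 0L; prop_part <- 0L
  acc_group <- 0L; prop_group <- 0L
  mig_events <- 0L
  acc_chain <- integer(D)   # participant-block acceptances per chain

  # --- main loop ------------------------------------------------------
  for (it in seq_len(config$n_burn + config$n_sample)) {
    burn <- it <= config$n_burn

    for (j in seq_len(J)) {
      if (burn && stats::runif(1) < config$migration_prob) {
        # migration sweep on participant block j
        mig_events <- mig_events + 1L
        k <- sample.int(D, 1L)
        ring <- sample.int(D, k)
        old_theta <- theta[ring, , j, drop = FALSE]
        old_ll <- ll[j, ring]
        for (m in seq_len(k)) {
          tgt <- ring[m]
          dr <- if (m == 1L) k else m - 1L
          prop <- old_theta[dr, , 1L]
          if (any(prop < lo | prop > hi)) next
          contrib <- stats::dnorm(prop, phi_mean[tgt, ], phi_sd[tgt, ],
                                  log = TRUE) - lognorm[tgt, ]
          ll_prop <- old_ll[dr]
          if (log(stats::runif(1)) <
              (ll_prop + sum(contrib)) - (ll[j, tgt] + sum(lpp[j, , tgt]))) {
            theta[tgt, , j] <- prop
            ll[j, tgt] <- ll_prop; lpp[j, , tgt] <- contrib
          }
        }
      } else {
        # sequential crossover over chains with live donors: accepted
        # moves are immediately visible to later chains' proposals
        for (i in seq_len(D)) {
          donors <- sample(seq_len(D)[-i], 2L)
          prop <- theta[i, , j] +
            gamma_p * (theta[donors[1L], , j] - theta[donors[2L], , j]) +
            stats::runif(P, -config$perturb, config$perturb)
          prop_part <- prop_part + 1L
          if (any(prop < lo | prop > hi)) next
          contrib <- stats::dnorm(prop, phi_mean[i, ], phi_sd[i, ],
                                  log = TRUE) - lognorm[i, ]
          ll_prop <- lba_loglik_chains(matrix(prop, 1L), pdat[[j]]$cellidx,
                                       pdat[[j]]$rt, pdat[[j]]$correct)[1L]
          if (!is.finite(ll_prop)) next
          if (log(stats::runif(1)) <
              (ll_prop + sum(contrib)) - (ll[j, i] + sum(lpp[j, , i]))) {
            theta[i, , j] <- prop
            ll[j, i] <- ll_prop; lpp[j, , i] <- contrib
            acc_part <- acc_part + 1L
            acc_chain[i] <- acc_chain[i] + 1L
          }
        }
      }
    }

    # group block: per-parameter (hypermean, hyperSD) sub-blocks
    if (burn && stats::runif(1) < config$migration_prob) {
      mig_events <- mig_events + 1L
      k <- sample.int(D, 1L)
      ring <- sample.int(D, k)
      old_mean <- phi_mean[ring, , drop = FALSE]
      old_sd <- phi_sd[ring, , drop = FALSE]
      for (m in seq_len(k)) {
        tgt <- ring[m]
        dr <- if (m == 1L) k else m - 1L
        pm <- old_mean[dr, ]; ps <- old_sd[dr, ]
        if (any(pm < hlo | pm > hhi) || any(ps <= 0)) next
        ln_prop <- trunc_lognorm(pm, ps, lo, hi)
        sdt_prop <- stats::dgamma(ps, shape = g_shape, rate = g_rate,
                                  log = TRUE)
        th <- matrix(theta[tgt, , ], P, J)
        contrib <- stats::dnorm(th, pm, ps, log = TRUE) - ln_prop  # P x J
        if (log(stats::runif(1)) <
            (sum(sdt_prop) + sum(contrib)) -
            (sum(sd_term[tgt, ]) + sum(lpp[, , tgt]))) {
          phi_mean[tgt, ] <- pm; phi_sd[tgt, ] <- ps
          lognorm[tgt, ] <- ln_prop; sd_term[tgt, ] <- sdt_prop
          lpp[, , tgt] <- t(contrib)
        }
      }
    } else {
      # sequential crossover per chain and per (hypermean, hyperSD) pair
      for (i in seq_len(D)) {
        for (p in seq_len(P)) {
          donors <- sample(seq_len(D)[-i], 2L)
          gamma_g <- stats::runif(1, 0.5, 1)
          mu_prop <- phi_mean[i, p] +
            gamma_g * (phi_mean[donors[1L], p] - phi_mean[donors[2L], p]) +
            stats::runif(1, -config$perturb, config$perturb)
          sd_prop <- phi_sd[i, p] +
            gamma_g * (phi_sd[donors[1L], p] - phi_sd[donors[2L], p]) +
            stats::runif(1, -config$perturb, config$perturb)
          prop_group <- prop_group + 1L
          if (mu_prop < hlo[p] || mu_prop > hhi[p] || sd_prop <= 0) next
          sdt_prop <- stats::dgamma(sd_prop, shape = g_shape, rate = g_rate,
                                    log = TRUE)
          ln_prop <- trunc_lognorm(mu_prop, sd_prop, lo[p], hi[p])
          contrib <- stats::dnorm(theta[i, p, ], mu_prop, sd_prop,
                                  log = TRUE) - ln_prop
          if (log(stats::runif(1)) <
              (sdt_prop + sum(contrib)) -
              (sd_term[i, p] + sum(lpp[, p, i]))) {
            phi_mean[i, p] <- mu_prop; phi_sd[i, p] <- sd_prop
            lognorm[i, p] <- ln_prop; sd_term[i, p] <- sdt_prop
            lpp[, p, i] <- contrib
            acc_group <- acc_group + 1L
          }
        }
      }
    }

    if (!burn && (it - config$n_burn) %% config$thin == 0L) {
      r <- (it - config$n_burn) %/% config$thin
      theta_store[r, , , ] <- theta
      phim_store[r, , ] <- phi_mean
      phis_store[r, , ] <- phi_sd
      ll_store[r, , ] <- t(ll)
    }
  }

  structure(list(theta = theta_store, phi_mean = phim_store,
                 phi_sd = phis_store, loglik = ll_store,
                 acceptance = list(
                   participant = acc_part / max(prop_part, 1L),
                   group = acc_group / max(prop_group, 1L),
                   migration_events = mig_events,
                   per_chain_participant = acc_chain /
                     max(prop_part / D, 1L)),
                 participants = names(pdat), model = model,
                 priors = priors, config = config,
                 gamma_participant = gamma_p,
                 data_hash = hash_trials(trials),
                 n_trials = nrow(trials)),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf("Hierarchical LBA fit (%s): %d participants, %d chains, %d retained iterations\n",
              x$model$variant, d[4], d[2], d[1]))
  cat(sprintf("  acceptance: participant %.3f, group %.3f; %d migration sweeps\n",
              x$acceptance$participant, x$acceptance$group,
              x$acceptance$migration_events))
  invisible(x)
}

# Stable hash of the fitted trial data, used to enforce the same-data
# precondition of model comparison.
hash_trials <- function(trials) {
  cols <- intersect(c("participant_id", "cell", "rt_s", "correct"),
                    names(trials))
  o <- do.call(order, trials[cols])
  s <- paste(utils::capture.output(utils::write.csv(trials[o, cols],
                                                    row.names = FALSE)),
             collapse = "\n")
  # polynomial rolling hash over the serialized rows (two co-prime moduli)
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(s)) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 1000000007
  }
  sprintf("%08x%08x", h1, h2)
}

#' Gelman-Rubin convergence diagnostics
#'
#' Univariate potential scale reduction factor per parameter and the
#' multivariate (Brooks-Gelman) PSRF over the parameter block.  Parameters
#' with zero within-chain variance are excluded from the multivariate
#' statistic with a warning.
#'
#' @param samples Array (iteration x chain x parameter) or matrix
#'   (iteration x chain, a single parameter).
#' @return List with `univariate` (named vector of R-hat values),
#'   `multivariate` (scalar Brooks-Gelman PSRF; `NA` when no usable
#'   parameters), `n`, `m` (iterations, chains).
#' @export
psrf <- function(samples) {
  if (is.matrix(samples)) samples <- array(samples, c(dim(samples), 1L))
  stopifnot(length(dim(samples)) == 3)
  n <- dim(samples)[1]; m <- dim(samples)[2]; P <- dim(samples)[3]
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 retained iterations")
  uni <- numeric(P)
  degenerate <- logical(P)
  for (p in seq_len(P)) {
    x <- samples[, , p]
    W <- mean(apply(x, 2, stats::var))
    Bn <- stats::var(colMeans(x))      # B/n
    if (W <= 0) {
      degenerate[p] <- TRUE
      uni[p] <- if (Bn <= 0) 1 else Inf
      next
    }
    uni[p] <- sqrt((n - 1) / n + Bn / W)
  }
  names(uni) <- dimnames(samples)[[3]]
  keep <- which(!degenerate)
  if (any(degenerate))
    warning(sum(degenerate),
            " zero-variance parameter(s) excluded from the multivariate PSRF")
  multivariate <- NA_real_
  if (length(keep) >= 1) {
    xs <- samples[, , keep, drop = FALSE]
    k <- length(keep)
    W <- matrix(0, k, k)
    means <- matrix(NA_real_, m, k)
    for (c in seq_len(m)) {
      xc <- matrix(xs[, c, ], n, k)
      W <- W + stats::cov(xc)
      means[c, ] <- colMeans(xc)
    }
    W <- W / m
    Bn <- stats::cov(means)            # B/n
    lambda1 <- tryCatch({
      e <- eigen(solve(W, Bn), only.values = TRUE)$values
      max(Re(e))
    }, error = function(e) NA_real_)
    multivariate <- sqrt((n - 1) / n + (m + 1) / m * lambda1)
  }
  list(univariate = uni, multivariate = multivariate, n = n, m = m)
}

#' Convergence summary of a hierarchical fit
#'
#' Computes the multivariate PSRF per participant (over that participant's
#' parameter block) and reports the median across participants — the
#' convergence summary used for the fits here, with threshold 1.05 — plus
#' the group-level multivariate PSRF and univariate R-hat values.
#'
#' @param fit A [run_sampler()] result.
#' @param threshold Convergence threshold for the reported flag.
#' @return List with `per_participant` (named vector of multivariate PSRFs),
#'   `median_mpsrf`, `group_mpsrf`, `univariate_group`, `converged`.
#' @export
hier_psrf <- function(fit, threshold = 1.05) {
  stopifnot(inherits(fit, "hier_fit"))
  J <- dim(fit$theta)[4]
  per <- vapply(seq_len(J), function(j)
    psrf(fit$theta[, , , j])$multivariate, numeric(1))
  names(per) <- fit$participants
  gsam <- array(c(fit$phi_mean, fit$phi_sd),
                c(dim(fit$phi_mean)[1:2], 2L * dim(fit$phi_mean)[3]))
  g <- psrf(gsam)
  med <- stats::median(per)
  list(per_participant = per, median_mpsrf = med,
       group_mpsrf = g$multivariate, univariate_group = g$univariate,
       converged = med < threshold, threshold = threshold)
}

#' Detect stuck chains
#'
#' A chain is flagged when its retained trace contains a run of at least
#' `window` consecutive iterations with an identical state (no accepted
#' proposal moved it).  The influence report summarizes each parameter's
#' pooled posterior mean and SD with and without the flagged chains.
#'
#' @param samples Array (iteration x chain x parameter).
#' @param window Minimum run length (iterations) that counts as stuck.
#' @return List with `flagged` (logical per chain), `max_run` (longest
#'   constant run per chain), and `influence` (data frame: parameter, mean /
#'   sd with all chains, mean / sd without flagged chains).
#' @export
detect_stuck <- function(samples, window = 50L) {
  if (is.matrix(samples)) samples <- array(samples, c(dim(samples), 1L))
  stopifnot(length(dim(samples)) == 3, window >= 2)
  n <- dim(samples)[1]; m <- dim(samples)[2]
  max_run <- integer(m)
  for (c in seq_len(m)) {
    x <- matrix(samples[, c, ], n)
    same <- rowSums(abs(x[-1, , drop = FALSE] - x[-n, , drop = FALSE])) == 0
    run <- 1L; best <- 1L
    for (s in same) {
      run <- if (s) run + 1L else 1L
      if (run > best) best <- run
    }
    max_run[c] <- best
  }
  flagged <- max_run >= window
  pn <- dimnames(samples)[[3]]
  if (is.null(pn)) pn <- paste0("p", seq_len(dim(samples)[3]))
  pool <- function(keep) {
    x <- samples[, keep, , drop = FALSE]
    t(apply(x, 3, function(v) c(mean = mean(v), sd = stats::sd(v))))
  }
  all_s <- pool(seq_len(m))
  wo <- if (any(flagged) && !all(flagged)) pool(which(!flagged)) else all_s
  influence <- data.frame(parameter = pn,
                          mean_all = all_s[, "mean"], sd_all = all_s[, "sd"],
                          mean_excl = wo[, "mean"], sd_excl = wo[, "sd"],
                          row.names = NULL)
  list(flagged = flagged, max_run = max_run, influence = influence)
}
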