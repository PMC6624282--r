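# Hierarchical model layer: the three model variants (which LBA parameters
# vary across design cells), participant-level parameter layouts, and all
# prior / hyperprior densities.

LBA_BASE_PARAMS <- c("v_correct", "delta_v", "s_error", "A", "B", "t0")
SHARED_PARAMS <- c("A", "s_error", "t0", "delta_v")

#' The six design cells of the study
#'
#' Two water-temperature conditions (Neutral, Warm) crossed with three
#' measurement moments (Baseline, Begin, End).  Baseline is the out-of-tub
#' measurement taken at the start of each session, so each session carries
#' its own baseline cell.
#'
#' @return A data frame with columns `condition`, `moment`, and `cell`
#'   (label `"condition:moment"`), 6 rows.
#' @export
design_cells <- function() {
  g <- expand.grid(moment = c("Baseline", "Begin", "End"),
                   condition = c("Neutral", "Warm"),
                   stringsAsFactors = FALSE)[, c("condition", "moment")]
  g$cell <- paste(g$condition, g$moment, sep = ":")
  g
}

#' Prior specification: participant-level bounds, hypermean bounds, hyperSD
#'
#' Participant-level parameters have uniform priors; their group-level
#' distributions are normals (truncated to the participant-level support)
#' described by a hypermean and a hyperSD.  Hypermeans have uniform priors,
#' hyperSDs have Gamma(shape = 1, rate = 1) priors (i.e. Exponential(1)).
#'
#' @return A list with matrices `participant` and `hypermean` (rows = base
#'   parameter, columns `lower`/`upper`) and `hypersd_shape`, `hypersd_rate`.
#' @export
prior_spec <- function() {
  part <- rbind(v_correct = c(-5, 20),
                delta_v   = c(0, 20),
                s_error   = c(0.1, 10),
                A         = c(0.01, 20),
                B         = c(0.01, 20),
                t0        = c(0.01, 0.5))
  hyp <- rbind(v_correct = c(0, 10),
               delta_v   = c(0, 10),
               s_error   = c(0.1, 5),
               A         = c(0.01, 10),
               B         = c(0.01, 10),
               t0        = c(0.01, 0.5))
  colnames(part) <- colnames(hyp) <- c("lower", "upper")
  list(participant = part, hypermean = hyp,
       hypersd_shape = 1, hypersd_rate = 1)
}

#' Build a hierarchical model variant
#'
#' The three variants differ in which LBA parameters are free to vary across
#' design cells: the drift rate (the sum of stimulus-driven and urgency
#' components, which are not separately identifiable), the threshold gap
#' `B`, or both.  `A`, `s_error`, `t0` and `delta_v` are always estimated
#' equal across cells.
#'
#' @param variant `"rate_only"`, `"threshold_only"`, or `"both"`.
#' @param cells Character vector of cell labels (see [design_cells()]) or a
#'   data frame with a `cell` column.
#' @return An object of class `lba_model`: variant name, cell labels, the
#'   participant-level parameter layout (`layout`: name, base parameter,
#'   cell), parameter count `n_params`, chain count `D = 3 * n_params`, and
#'   an integer index matrix `cell_index` (cells x base parameters) mapping
#'   each design cell to positions in the participant parameter vector.
#' @export
build_model <- function(variant = c("both", "rate_only", "threshold_only"),
                        cells = design_cells()) {
  variant <- match.arg(variant)
  if (is.data.frame(cells)) cells <- cells$cell
  cells <- as.character(cells)
  if (!length(cells)) stop("cells must be nonempty")
  if (anyDuplicated(cells)) stop("duplicate cell labels")
  free <- switch(variant,
                 rate_only = "v_correct",
                 threshold_only = "B",
                 both = c("v_correct", "B"))
  shared <- setdiff(LBA_BASE_PARAMS, free)
  stopifnot(setequal(intersect(shared, SHARED_PARAMS), SHARED_PARAMS))
  layout <- rbind(
    data.frame(name = shared, base = shared, cell = NA_character_),
    do.call(rbind, lapply(free, function(p)
      data.frame(name = paste(p, cells, sep = "|"), base = p, cell = cells)))
  )
  rownames(layout) <- NULL
  n_params <- nrow(layout)
  cell_index <- matrix(NA_integer_, nrow = length(cells),
                       ncol = length(LBA_BASE_PARAMS),
                       dimnames = list(cells, LBA_BASE_PARAMS))
  for (p in LBA_BASE_PARAMS) {
    if (p %in% shared) {
      cell_index[, p] <- match(p, layout$name)
    } else {
      cell_index[, p] <- match(paste(p, cells, sep = "|"), layout$name)
    }
  }
  structure(list(variant = variant, cells = cells, free = free,
                 shared = shared, layout = layout, n_params = n_params,
                 D = 3L * n_params, cell_index = cell_index),
            class = "lba_model")
}

#' @export
print.lba_model <- function(x, ...) {
  cat(sprintf("Hierarchical LBA model '%s': %d cells, %d participant-level parameters, D = %d chains\n",
              x$variant, length(x$cells), x$n_params, x$D))
  cat("  free across cells:", paste(x$free, collapse = ", "), "\n")
  cat("  shared:", paste(x$shared, collapse = ", "), "\n")
  invisible(x)
}

# Bounds of the participant-level uniform prior for each entry of the
# participant parameter vector, in layout order.
participant_bounds <- function(model, priors = prior_spec()) {
  b <- priors$participant[model$layout$base, , drop = FALSE]
  rownames(b) <- model$layout$name
  b
}

# Bounds of the hypermean priors in layout order.
hypermean_bounds <- function(model, priors = prior_spec()) {
  b <- priors$hypermean[model$layout$base, , drop = FALSE]
  rownames(b) <- model$layout$name
  b
}

#' Resolve a participant parameter vector to LBA parameters for one cell
#'
#' @param theta Named numeric vector in the model's layout order.
#' @param model An [build_model()] object.
#' @param cell A cell label present in the model.
#' @return An [lba_params()] object.
#' @export
cell_params <- function(theta, model, cell) {
  idx <- model$cell_index[cell, ]
  theta <- unname(theta)
  lba_params(A = theta[idx[["A"]]], B = theta[idx[["B"]]],
             v_correct = theta[idx[["v_correct"]]],
             delta_v = theta[idx[["delta_v"]]],
             s_error = theta[idx[["s_error"]]],
             t0 = theta[idx[["t0"]]])
}

#' Participant-level log prior density
#'
#' Each participant-level parameter is a priori normal with the group-level
#' hypermean and hyperSD, truncated to the participant-level uniform
#' support.  Returns `-Inf` when any parameter falls outside its support.
#'
#' @param theta Named numeric vector of participant parameters (layout
#'   order).
#' @param phi List with numeric vectors `mean` and `sd` of the same length
#'   as `theta` (group-level parameters for each participant-level
#'   parameter).
#' @param model An [build_model()] object.
#' @param priors A [prior_spec()] list.
#' @return Scalar log density.
#' @export
log_prior_participant <- function(theta, phi, model, priors = prior_spec()) {
  b <- participant_bounds(model, priors)
  if (any(theta < b[, "lower"] | theta > b[, "upper"])) return(-Inf)
  if (any(phi$sd <= 0)) return(-Inf)
  z <- stats::dnorm(theta, phi$mean, phi$sd, log = TRUE)
  sum(z) - sum(trunc_lognorm(phi$mean, phi$sd, b[, "lower"], b[, "upper"]))
}

# Log truncation mass of the participant-level support under the group
# normal: the renormalization that makes the participant-level truncated
# normal a proper conditional density.
trunc_lognorm <- function(mu, sd, lo, hi) {
  log(pmax(stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd), 1e-300))
}

# Same truncated-normal log prior for a whole population: theta_mat is
# J participants x P params; phi as above.  Returns scalar sum (or -Inf).
log_prior_population <- function(theta_mat, phi, model, priors = prior_spec()) {
  b <- participant_bounds(model, priors)
  lo <- matrix(b[, "lower"], nrow(theta_mat), ncol(theta_mat), byrow = TRUE)
  hi <- matrix(b[, "upper"], nrow(theta_mat), ncol(theta_mat), byrow = TRUE)
  if (any(theta_mat < lo | theta_mat > hi)) return(-Inf)
  if (any(phi$sd <= 0)) return(-Inf)
  mu <- matrix(phi$mean, nrow(theta_mat), ncol(theta_mat), byrow = TRUE)
  sd <- matrix(phi$sd, nrow(theta_mat), ncol(theta_mat), byrow = TRUE)
  z <- stats::dnorm(theta_mat, mu, sd, log = TRUE)
  sum(z) - nrow(theta_mat) *
    sum(trunc_lognorm(phi$mean, phi$sd, b[, "lower"], b[, "upper"]))
}

#' Group-level log hyperprior density
#'
#' Uniform priors on the hypermeans, Gamma(1, 1) priors on the hyperSDs.
#'
#' @param phi List with `mean` and `sd` vectors (layout order).
#' @param model An [build_model()] object.
#' @param priors A [prior_spec()] list.
#' @return Scalar log density; `-Inf` outside support.
#' @export
log_hyperprior <- function(phi, model, priors = prior_spec()) {
  b <- hypermean_bounds(model, priors)
  if (any(phi$mean < b[, "lower"] | phi$mean > b[, "upper"])) return(-Inf)
  if (any(phi$sd <= 0)) return(-Inf)
  sum(-log(b[, "upper"] - b[, "lower"])) +
    sum(stats::dgamma(phi$sd, shape = priors$hypersd_shape,
                      rate = priors$hypersd_rate, log = TRUE))
}

#' Dataset log likelihood under a hierarchical layout
#'
#' Sums the trial log likelihood over all choice trials, resolving each
#' participant's parameter vector to cell-level LBA parameters.
#'
#' @param trials Data frame of choice trials with columns `participant_id`,
#'   `cell`, `rt_s`, `correct` (logical or 0/1).
#' @param theta_all Named list: one named parameter vector per participant.
#' @param model An [build_model()] object.
#' @return Scalar log likelihood; 0 for an empty trial list.
#' @export
dataset_loglik <- function(trials, theta_all, model) {
  if (!nrow(trials)) return(0)
  ids <- unique(trials$participant_id)
  missing <- setdiff(as.character(ids), names(theta_all))
  if (length(missing))
    stop("no parameters for participant(s): ", paste(missing, collapse = ", "))
  total <- 0
  for (id in ids) {
    tr <- trials[trials$participant_id == id, ]
    theta <- theta_all[[as.character(id)]]
    for (cl in unique(tr$cell)) {
      if (!cl %in% model$cells) stop("cell not in model layout: ", cl)
      sub <- tr[tr$cell == cl, ]
      p <- cell_params(theta, model, cl)
      resp <- ifelse(as.logical(sub$correct), "target", "foil")
      total <- total + sum(trial_loglik(sub$rt_s, resp, p))
    }
  }
  total
}

# Compact per-participant data representation used by the sampler: list with
# rt, correct (logical), cell_id (integer into model$cells), n.
participant_data <- function(trials, model) {
  ids <- sort(unique(as.character(trials$participant_id)))
  out <- lapply(ids, function(id) {
    tr <- trials[as.character(trials$participant_id) == id, ]
    cid <- match(tr$cell, model$cells)
    if (anyNA(cid)) stop("trial cell not covered by model layout")
    ci <- model$cell_index[cid, c("A", "B", "v_correct", "delta_v",
                                  "s_error", "t0"), drop = FALSE]
    list(rt = as.numeric(tr$rt_s), correct = as.logical(tr$correct),
         cell_id = cid, cellidx = ci, n = nrow(tr))
  })
  names(out) <- ids
  out
}

# Chain-batched participant log likelihood: theta_mat is chains x params
# (layout order); returns one summed log likelihood per chain.  All density
# work happens in a single set of vectorized normal calls over the
# (chains x trials) grid.
participant_loglik_matrix <- function(theta_mat, pdat, model) {
  ci <- model$cell_index
  D <- nrow(theta_mat); n <- pdat$n
  A   <- theta_mat[, ci[pdat$cell_id, "A"], drop = FALSE]
  B   <- theta_mat[, ci[pdat$cell_id, "B"], drop = FALSE]
  v_t <- theta_mat[, ci[pdat$cell_id, "v_correct"], drop = FALSE]
  v_f <- v_t - theta_mat[, ci[pdat$cell_id, "delta_v"], drop = FALSE]
  s_f <- theta_mat[, ci[pdat$cell_id, "s_error"], drop = FALSE]
  t0  <- theta_mat[, ci[pdat$cell_id, "t0"], drop = FALSE]
  bthr <- A + B
  rt <- matrix(pdat$rt, D, n, byrow = TRUE)
  tau <- rt - t0
  bad_rows <- rowSums(tau <= 0) > 0
  tau[tau <= 0] <- 1e-6   # placeholder; rows are forced to -Inf below
  ts_t <- tau
  ts_f <- tau * s_f
  z1t <- (bthr - A - tau * v_t) / ts_t
  z2t <- (bthr - tau * v_t) / ts_t
  z1f <- (bthr - A - tau * v_f) / ts_f
  z2f <- (bthr - tau * v_f) / ts_f
  p_z1t <- stats::pnorm(z1t); p_z2t <- stats::pnorm(z2t)
  p_z1f <- stats::pnorm(z1f); p_z2f <- stats::pnorm(z2f)
  d_z1t <- stats::dnorm(z1t); d_z2t <- stats::dnorm(z2t)
  d_z1f <- stats::dnorm(z1f); d_z2f <- stats::dnorm(z2f)
  pdf_t <- pmax((v_t * (p_z2t - p_z1t) + (d_z1t - d_z2t)) / A, 0)
  pdf_f <- pmax((v_f * (p_z2f - p_z1f) + s_f * (d_z1f - d_z2f)) / A, 0)
  cdf_t <- pmin(pmax(1 + ((bthr - A - tau * v_t) / A) * p_z1t -
                       ((bthr - tau * v_t) / A) * p_z2t +
                       (ts_t / A) * (d_z1t - d_z2t), 0), 1)
  cdf_f <- pmin(pmax(1 + ((bthr - A - tau * v_f) / A) * p_z1f -
                       ((bthr - tau * v_f) / A) * p_z2f +
                       (ts_f / A) * (d_z1f - d_z2f), 0), 1)
  corr <- matrix(pdat$correct, D, n, byrow = TRUE)
  dens <- pdf_f * (1 - cdf_t)
  dens[corr] <- (pdf_t * (1 - cdf_f))[corr]
  out <- rowSums(log(pmax(dens, DENSITY_FLOOR)))
  out[bad_rows] <- -Inf
  out
}

# Fast participant log likelihood for the sampler: theta is an unnamed
# numeric vector in layout order, pdat from participant_data().
participant_loglik_fast <- function(theta, pdat, model) {
  ci <- model$cell_index
  A    <- theta[ci[pdat$cell_id, "A"]]
  B    <- theta[ci[pdat$cell_id, "B"]]
  v_c  <- theta[ci[pdat$cell_id, "v_correct"]]
  dv   <- theta[ci[pdat$cell_id, "delta_v"]]
  s_e  <- theta[ci[pdat$cell_id, "s_error"]]
  t0   <- theta[ci[pdat$cell_id, "t0"]]
  lba_sumloglik_flat(pdat$rt, pdat$correct,
                     A = A, bthr = A + B, v_t = v_c, v_f = v_c - dv,
                     s_t = rep(1, pdat$n), s_f = s_e, t0 = t0)
}
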