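# Synthetic study generator: interval reproductions from a
# pacemaker-accumulator clock, binomial flicker stimuli, LBA choice trials,
# and the full two-task study with clock speed-up in the Warm-End cell and
# a participant-level coupling between clock speed-up and threshold drop.

#' Pacemaker-clock generative parameters
#'
#' A pacemaker emits pulses at a rate that scales with core temperature; a
#' learned interval corresponds to a fixed pulse count, so when the current
#' pacemaker rate exceeds the rate at learning (rate ratio > 1) the count is
#' reached sooner and the interval is underproduced.  Reproductions are
#' `target * bias / rate_ratio` times multiplicative lognormal noise with
#' coefficient of variation `cv` (scalar timing).
#'
#' @param rate_ratio Named numeric vector: current pacemaker rate divided by
#'   the rate at learning, one entry per design cell (>= 0, and exactly 1 in
#'   Baseline cells).
#' @param bias Multiplicative underproduction tendency, `0 < bias <= 1`.
#' @param cv Coefficient of variation of reproductions (>= 0).
#' @return A list of class `clock_params`.
#' @export
clock_params <- function(rate_ratio = c("Neutral:Baseline" = 1,
                                        "Neutral:Begin" = 1,
                                        "Neutral:End" = 1,
                                        "Warm:Baseline" = 1,
                                        "Warm:Begin" = 1.03,
                                        "Warm:End" = 1.10),
                         bias = 0.95, cv = 0.10) {
  if (any(!is.finite(rate_ratio)) || any(rate_ratio <= 0))
    stop("rate_ratio entries must be finite and > 0")
  base <- grepl(":Baseline$", names(rate_ratio))
  if (any(base) && any(rate_ratio[base] != 1))
    stop("rate_ratio must equal 1 in Baseline cells")
  if (!is.finite(bias) || bias <= 0 || bias > 1)
    stop("bias must be in (0, 1]")
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0")
  structure(list(rate_ratio = rate_ratio, bias = bias, cv = cv),
            class = "clock_params")
}

# Deterministic child seed derivation from a master seed and a stream tag;
# stays inside the 32-bit signed integer range.
derive_seed <- function(master, ...) {
  tag <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Simulate interval reproductions from the pacemaker clock
#'
#' @param clock A [clock_params()] object.
#' @param cell Design-cell label (must be present in `clock$rate_ratio`).
#' @param target_s Learned target interval, seconds (> 0).
#' @param n Number of trials.
#' @param seed Integer seed.
#' @param participant_id Identifier recorded in the output.
#' @return Data frame of timing trials: `participant_id`, `cell`,
#'   `target_s`, `reproduction_s`.
#' @export
simulate_reproductions <- function(clock, cell, target_s = 1.0, n, seed,
                                   participant_id = "p1") {
  stopifnot(inherits(clock, "clock_params"), n >= 1)
  if (!is.finite(target_s) || target_s <= 0)
    stop("target_s must be > 0")
  if (!cell %in% names(clock$rate_ratio))
    stop("unknown cell: ", cell)
  rr <- clock$rate_ratio[[cell]]
  if (rr <= 0) stop("rate_ratio must be > 0")
  set.seed(seed)
  mu <- target_s * clock$bias / rr
  if (clock$cv > 0) {
    # lognormal with mean mu and coefficient of variation cv
    sdlog <- sqrt(log(1 + clock$cv^2))
    meanlog <- log(mu) - sdlog^2 / 2
    rep_s <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    rep_s <- rep(mu, n)
  }
  data.frame(participant_id = participant_id, cell = cell,
             target_s = target_s, reproduction_s = rep_s,
             stringsAsFactors = FALSE)
}

#' Simulate one flicker-discrimination stimulus
#'
#' Two circles flicker independently; each frame, a circle is on with its
#' own Bernoulli rate (target 0.7 vs foil 0.3 in the task emulated here).
#' The target's side is randomized per trial.
#'
#' @param rate_target,rate_foil Per-frame on-probabilities in `[0, 1]`.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return List of class `stimulus_frames`: `frames` (n_frames x 2 matrix of
#'   0/1, columns left/right), `rate_target`, `rate_foil`, `side_of_target`.
#' @export
simulate_flicker <- function(rate_target = 0.7, rate_foil = 0.3,
                             n_frames, seed) {
  if (!is.finite(rate_target) || rate_target < 0 || rate_target > 1 ||
      !is.finite(rate_foil) || rate_foil < 0 || rate_foil > 1)
    stop("rates must lie in [0, 1]")
  stopifnot(n_frames >= 1)
  set.seed(seed)
  side <- sample(c("left", "right"), 1L)
  target_col <- stats::rbinom(n_frames, 1L, rate_target)
  foil_col <- stats::rbinom(n_frames, 1L, rate_foil)
  frames <- if (side == "left") cbind(left = target_col, right = foil_col)
            else cbind(left = foil_col, right = target_col)
  structure(list(frames = frames, rate_target = rate_target,
                 rate_foil = rate_foil, side_of_target = side),
            class = "stimulus_frames")
}

#' Simulate choice trials from the LBA
#'
#' Each trial draws a start point uniform on `[0, A]` and a drift rate
#' normal with the accumulator's mean and SD for both accumulators; the
#' response is the accumulator that crosses threshold `b = A + B` first and
#' the RT is `t0` plus its crossing time.  Draws where neither drift is
#' positive are re-drawn (the conditional-on-response model matching the
#' un-normalized likelihood); the frequency of such re-draws is returned as
#' an attribute.  Trials slower than the deadline are flagged and retained.
#'
#' @param params An [lba_params()] object.
#' @param n Number of trials.
#' @param deadline_s Response deadline, seconds.
#' @param seed Integer seed.
#' @param cell,participant_id Labels recorded in the output.
#' @return Data frame of choice trials: `participant_id`, `cell`, `rt_s`,
#'   `response` (`"target"`/`"foil"`), `correct`, `deadline_s`,
#'   `missed_deadline`; attribute `redraw_rate` gives the fraction of drift
#'   draws rejected for being all-negative.
#' @export
simulate_choices <- function(params, n, deadline_s = 1.0, seed,
                             cell = "Neutral:Baseline", participant_id = "p1") {
  stopifnot(inherits(params, "lba_params"), n >= 1)
  set.seed(seed)
  v <- effective_drifts(params)
  s <- c(params$s_correct, params$s_error)
  need <- n
  rt <- numeric(0); resp <- character(0)
  n_drawn <- 0L; n_rejected <- 0L
  while (need > 0) {
    m <- need
    start_t <- stats::runif(m, 0, params$A)
    start_f <- stats::runif(m, 0, params$A)
    d_t <- stats::rnorm(m, v[["target"]], s[1])
    d_f <- stats::rnorm(m, v[["foil"]], s[2])
    n_drawn <- n_drawn + m
    ok <- d_t > 0 | d_f > 0
    n_rejected <- n_rejected + sum(!ok)
    if (!any(ok)) next
    tt <- ifelse(d_t[ok] > 0, (params$b - start_t[ok]) / d_t[ok], Inf)
    tf <- ifelse(d_f[ok] > 0, (params$b - start_f[ok]) / d_f[ok], Inf)
    win_t <- tt <= tf
    rt <- c(rt, params$t0 + pmin(tt, tf))
    resp <- c(resp, ifelse(win_t, "target", "foil"))
    need <- n - length(rt)
  }
  out <- data.frame(participant_id = participant_id, cell = cell,
                    rt_s = rt, response = resp,
                    correct = resp == "target",
                    deadline_s = deadline_s,
                    missed_deadline = rt > deadline_s,
                    stringsAsFactors = FALSE)
  attr(out, "redraw_rate") <- n_rejected / n_drawn
  out
}

#' Group-level ground truth for the synthetic study
#'
#' Per-cell group means of the LBA parameters, their between-participant
#' SDs, and the clock truth, set to emulate the study's hypothesized
#' structure: the clock speeds up in the Warm-End cell and the threshold
#' gap `B` drops there in proportion to each participant's own speed-up.
#' Values are chosen to produce response times of a few hundred
#' milliseconds against a 1 s deadline with accuracy well above chance.
#'
#' @param cells Character vector of cell labels.
#' @param coupling Slope linking a participant's clock speed-up
#'   `(rate_ratio - 1)` to that participant's drop in `B` in Warm in-tub
#'   cells (evidence units per unit rate-ratio excess).
#' @param coupling_noise_sd SD of the noise on the coupled threshold drop.
#' @return List of class `study_truth` with `group_mean` / `group_sd`
#'   (matrices: base parameter x cell), `clock` ([clock_params()]),
#'   `rate_ratio_sd` (between-participant SD of the Warm-End speed-up),
#'   `coupling`, `coupling_noise_sd`.
#' @export
study_truth <- function(cells = design_cells()$cell, coupling = 2.0,
                        coupling_noise_sd = 0.05) {
  base_mean <- c(v_correct = 3.2, delta_v = 1.8, s_error = 1.0,
                 A = 0.6, B = 0.9, t0 = 0.18)
  base_sd <- c(v_correct = 0.5, delta_v = 0.4, s_error = 0.15,
               A = 0.12, B = 0.18, t0 = 0.03)
  gm <- matrix(base_mean, nrow = 6, ncol = length(cells),
               dimnames = list(names(base_mean), cells))
  gs <- matrix(base_sd, nrow = 6, ncol = length(cells),
               dimnames = list(names(base_sd), cells))
  structure(list(group_mean = gm, group_sd = gs,
                 clock = clock_params(),
                 rate_ratio_sd = 0.04,
                 coupling = coupling,
                 coupling_noise_sd = coupling_noise_sd),
            class = "study_truth")
}

#' Generate a complete synthetic study
#'
#' Draws per-participant clock and LBA parameters from the group truth and
#' simulates both tasks in every design cell.  Each participant's Warm-End
#' pacemaker rate ratio is drawn around the group value; their threshold gap
#' `B` in the Warm in-tub cells is reduced by `coupling * (rate_ratio - 1)`
#' plus noise, so the cross-task correlation between reproduction change and
#' threshold change is recoverable by the downstream fit.  Identical seeds
#' give identical datasets.
#'
#' @param truth A [study_truth()] object.
#' @param n_participants Number of participants (>= 2).
#' @param n_trials_per_cell Trials per task per cell (>= 1).
#' @param seed Master seed; per-participant, per-cell, per-task child
#'   streams are derived from it deterministically.
#' @param cells Cell labels to generate (default all 6).
#' @param target_s Learned interval, seconds.
#' @param deadline_s Choice deadline, seconds.
#' @return List of class `synthetic_study`: `timing` and `choice` trial data
#'   frames (the trial-table dialect of [write_trials()]), and
#'   `ground_truth` (per-participant parameter record plus the generative
#'   configuration and master seed).
#' @export
generate_study <- function(truth = study_truth(), n_participants = 27,
                           n_trials_per_cell = 60, seed = 1,
                           cells = NULL, target_s = 1.0, deadline_s = 1.0) {
  stopifnot(inherits(truth, "study_truth"),
            n_participants >= 2, n_trials_per_cell >= 1)
  if (any(truth$group_sd < 0)) stop("negative group-truth SD")
  if (is.null(cells)) cells <- colnames(truth$group_mean)
  cells <- as.character(cells)
  pb <- prior_spec()$participant
  ids <- sprintf("p%02d", seq_len(n_participants))
  all_cells <- design_cells()
  timing <- list(); choice <- list(); truth_rows <- list()
  for (pi in seq_along(ids)) {
    id <- ids[pi]
    set.seed(derive_seed(seed, "participant", id))
    # participant clock: Warm in-tub cells get an individual speed-up
    rr <- truth$clock$rate_ratio
    warm_excess <- pmax(stats::rnorm(1, rr[["Warm:End"]] - 1,
                                     truth$rate_ratio_sd), 0)
    begin_frac <- if (rr[["Warm:End"]] > 1)
      (rr[["Warm:Begin"]] - 1) / (rr[["Warm:End"]] - 1) else 0
    rr[["Warm:End"]] <- 1 + warm_excess
    rr[["Warm:Begin"]] <- 1 + begin_frac * warm_excess
    clock_i <- clock_params(rate_ratio = rr, bias = truth$clock$bias,
                            cv = truth$clock$cv)
    # participant LBA parameters: one deviation per base parameter, shared
    # across cells (cell differences enter through the group means and the
    # coupled threshold drop below), truncated into prior support
    dev <- stats::rnorm(nrow(truth$group_mean), 0, truth$group_sd[, 1])
    theta <- truth$group_mean + dev
    theta <- pmin(pmax(theta, pb[rownames(theta), "lower"] + 1e-6),
                  pb[rownames(theta), "upper"] - 1e-6)
    # couple the Warm in-tub threshold drop to the participant's speed-up
    d_B <- truth$coupling * warm_excess +
      stats::rnorm(1, 0, truth$coupling_noise_sd)
    for (cl in intersect(c("Warm:Begin", "Warm:End"), colnames(theta))) {
      frac <- if (cl == "Warm:Begin") begin_frac else 1
      theta["B", cl] <- min(max(theta["B", cl] - frac * d_B,
                                pb["B", "lower"] + 1e-6),
                            pb["B", "upper"] - 1e-6)
    }
    for (cl in cells) {
      rep_df <- simulate_reproductions(
        clock_i, cell = cl, target_s = target_s, n = n_trials_per_cell,
        seed = derive_seed(seed, id, cl, "timing"), participant_id = id)
      cond <- all_cells$condition[match(cl, all_cells$cell)]
      rep_df$session <- session_of(pi, cond)
      timing[[length(timing) + 1L]] <- rep_df
      params <- lba_params(A = theta["A", cl], B = theta["B", cl],
                           v_correct = theta["v_correct", cl],
                           delta_v = theta["delta_v", cl],
                           s_error = theta["s_error", cl],
                           t0 = theta["t0", cl])
      ch <- simulate_choices(params, n = n_trials_per_cell,
                             deadline_s = deadline_s,
                             seed = derive_seed(seed, id, cl, "choice"),
                             cell = cl, participant_id = id)
      ch$session <- session_of(pi, cond)
      choice[[length(choice) + 1L]] <- ch
    }
    truth_rows[[pi]] <- data.frame(
      participant_id = id,
      rate_ratio_warm_end = 1 + warm_excess,
      delta_B_warm = d_B,
      t(as.vector(theta)),
      stringsAsFactors = FALSE)
    names(truth_rows[[pi]])[-(1:3)] <-
      paste(rep(rownames(theta), times = ncol(theta)),
            rep(colnames(theta), each = nrow(theta)), sep = "|")
  }
  structure(list(
    timing = do.call(rbind, timing),
    choice = do.call(rbind, choice),
    ground_truth = list(
      participants = do.call(rbind, truth_rows),
      truth = truth, seed = seed, cells = cells,
      n_participants = n_participants,
      n_trials_per_cell = n_trials_per_cell,
      target_s = target_s, deadline_s = deadline_s)),
    class = "synthetic_study")
}

# Session assignment with counterbalanced condition order: odd participants
# do Neutral first, even participants Warm first.
session_of <- function(participant_index, condition) {
  neutral_first <- participant_index %% 2L == 1L
  if (condition == "Neutral") ifelse(neutral_first, 1L, 2L)
  else ifelse(neutral_first, 2L, 1L)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d participants, %d timing + %d choice trials across %d cells (seed %s)\n",
              x$ground_truth$n_participants, nrow(x$timing), nrow(x$choice),
              length(x$ground_truth$cells), x$ground_truth$seed))
  invisible(x)
}
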