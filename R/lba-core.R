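# Linear Ballistic Accumulator kernel: single-accumulator crossing-time
# distributions, defective densities for two-choice data, choice
# probabilities, trial log-likelihoods, and the additive-urgency /
# linearly-collapsing-threshold equivalence map.  Pure computation, no I/O.

DENSITY_FLOOR <- 1e-300

#' Construct and validate LBA parameters for one design cell
#'
#' The model is parameterized the way it is usually estimated: the start
#' point of each accumulator is uniform on `[0, A]`, the response threshold
#' is `b = A + B` (so `B` is the gap between the top of the start-point
#' range and the threshold), drift rates are normal across trials with mean
#' `v` and standard deviation `s`.  The accumulator matching the stimulus
#' ("target") has mean drift `v_correct` and drift SD `s_correct` (fixed at
#' 1 as the scaling constraint); the mismatching ("foil") accumulator has
#' mean drift `v_correct - delta_v` and SD `s_error`.  An additive urgency
#' component `urgency` is added to both mean drifts; it is stored separately
#' only so that the equivalence with a linearly collapsing threshold can be
#' exercised explicitly — in the data likelihood only the sums matter.
#'
#' @param A Start-point range (> 0), evidence units.
#' @param B Threshold minus start-point range (> 0); threshold `b = A + B`.
#' @param v_correct Mean drift of the accumulator matching the stimulus,
#'   evidence units per second.
#' @param delta_v Drift difference `v_correct - v_error` (>= 0).
#' @param s_error Across-trial drift SD of the error accumulator (> 0).
#' @param t0 Non-decision time, seconds (> 0).
#' @param urgency Additive drift component applied to both accumulators
#'   (default 0), evidence units per second.
#' @param s_correct Drift SD of the correct accumulator; fixed at 1 by the
#'   scaling constraint and validated as such.
#' @return An object of class `lba_params` (a named list).
#' @export
lba_params <- function(A, B, v_correct, delta_v, s_error, t0,
                       urgency = 0, s_correct = 1) {
  vals <- c(A = A, B = B, v_correct = v_correct, delta_v = delta_v,
            s_error = s_error, t0 = t0, urgency = urgency,
            s_correct = s_correct)
  if (any(!is.finite(vals)))
    stop("all LBA parameters must be finite")
  if (A <= 0) stop("A must be > 0")
  if (B <= 0) stop("B must be > 0 (threshold b = A + B must exceed A)")
  if (delta_v < 0) stop("delta_v must be >= 0")
  if (s_error <= 0) stop("s_error must be > 0")
  if (t0 <= 0) stop("t0 must be > 0")
  if (s_correct != 1)
    stop("s_correct is fixed at 1 (scaling constraint)")
  structure(list(A = A, B = B, b = A + B, v_correct = v_correct,
                 delta_v = delta_v, v_error = v_correct - delta_v,
                 s_error = s_error, s_correct = s_correct,
                 t0 = t0, urgency = urgency),
            class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA cell parameters:\n")
  cat(sprintf("  A = %.4g, B = %.4g (b = %.4g), v_correct = %.4g, delta_v = %.4g\n",
              x$A, x$B, x$b, x$v_correct, x$delta_v))
  cat(sprintf("  s_error = %.4g, s_correct = %g, t0 = %.4g, urgency = %.4g\n",
              x$s_error, x$s_correct, x$t0, x$urgency))
  invisible(x)
}

# Effective mean drifts (stimulus + urgency) for the two accumulators.
effective_drifts <- function(params) {
  c(target = params$v_correct + params$urgency,
    foil   = params$v_error + params$urgency)
}

#' Crossing-time CDF of a single linear ballistic accumulator
#'
#' Probability that an accumulator with start point uniform on `[0, A]` and
#' drift normal with mean `v` and SD `s` has reached threshold `b` by
#' accumulation time `t` (time counted from the start of accumulation, i.e.
#' excluding non-decision time).  As `t` grows the CDF approaches
#' `pnorm(v / s)`: trials whose drift draw is non-positive never cross.
#'
#' Vectorized over `t` and `v` (recycled against each other).
#'
#' @param t Accumulation time(s), seconds; values `<= 0` give 0.
#' @param A Start-point range (> 0).
#' @param b Threshold (> A).
#' @param v Mean drift(s).
#' @param s Drift SD (> 0).
#' @return Probabilities in `[0, 1]`.
#' @export
accumulator_cdf <- function(t, A, b, v, s) {
  if (A <= 0 || b <= A || s <= 0)
    stop("require A > 0, b > A, s > 0")
  n <- max(length(t), length(v))
  t <- rep_len(t, n); v <- rep_len(v, n)
  out <- numeric(n)
  pos <- which(t > 0)
  if (length(pos)) {
    tp <- t[pos]; vp <- v[pos]
    ts <- tp * s
    z1 <- (b - A - tp * vp) / ts
    z2 <- (b - tp * vp) / ts
    val <- 1 +
      ((b - A - tp * vp) / A) * stats::pnorm(z1) -
      ((b - tp * vp) / A) * stats::pnorm(z2) +
      (ts / A) * (stats::dnorm(z1) - stats::dnorm(z2))
    out[pos] <- pmin(pmax(val, 0), 1)
  }
  out
}

#' Crossing-time density of a single linear ballistic accumulator
#'
#' Density of the threshold-crossing time for the accumulator described in
#' [accumulator_cdf()].  The density is defective: it integrates over
#' `(0, Inf)` to `pnorm(v / s)`, the probability of a positive drift draw.
#'
#' @inheritParams accumulator_cdf
#' @return Densities (1/s), `>= 0`; 0 for `t <= 0`.
#' @export
accumulator_pdf <- function(t, A, b, v, s) {
  if (A <= 0 || b <= A || s <= 0)
    stop("require A > 0, b > A, s > 0")
  n <- max(length(t), length(v))
  t <- rep_len(t, n); v <- rep_len(v, n)
  out <- numeric(n)
  pos <- which(t > 0)
  if (length(pos)) {
    tp <- t[pos]; vp <- v[pos]
    ts <- tp * s
    z1 <- (b - A - tp * vp) / ts
    z2 <- (b - tp * vp) / ts
    val <- (vp * (stats::pnorm(z2) - stats::pnorm(z1)) +
            s * (stats::dnorm(z1) - stats::dnorm(z2))) / A
    out[pos] <- pmax(val, 0)
  }
  out
}

#' Defective RT density for one response
#'
#' Density of observing response `response` at time `rt_s`: the winning
#' accumulator's crossing density times the probability that the losing
#' accumulator has not yet crossed, evaluated at accumulation time
#' `rt_s - t0` with effective drifts (stimulus + urgency).  The density is
#' un-normalized: no division by the probability that at least one drift is
#' positive.  At the parameter ranges fitted here that all-negative mass is
#' negligible; [all_negative_mass()] reports it as a diagnostic.
#'
#' @param rt_s Response time(s) in seconds; values `<= t0` give density 0.
#' @param response `"target"` (correct) or `"foil"` (error); scalar or
#'   vector recycled against `rt_s`.
#' @param params An [lba_params()] object.
#' @return Defective densities (1/s).
#' @export
defective_pdf <- function(rt_s, response, params) {
  stopifnot(inherits(params, "lba_params"))
  if (!all(response %in% c("target", "foil")))
    stop("unknown response label; expected 'target' or 'foil'")
  n <- max(length(rt_s), length(response))
  rt_s <- rep_len(rt_s, n); response <- rep_len(response, n)
  v <- effective_drifts(params)
  s <- c(target = params$s_correct, foil = params$s_error)
  tau <- rt_s - params$t0
  win <- ifelse(response == "target", "target", "foil")
  lose <- ifelse(response == "target", "foil", "target")
  out <- numeric(n)
  for (w in c("target", "foil")) {
    idx <- which(win == w)
    if (!length(idx)) next
    l <- if (w == "target") "foil" else "target"
    out[idx] <- accumulator_pdf(tau[idx], params$A, params$b, v[[w]], s[[w]]) *
      (1 - accumulator_cdf(tau[idx], params$A, params$b, v[[l]], s[[l]]))
  }
  out
}

#' Probability that both drift draws are non-positive
#'
#' The mass not accounted for by the two defective densities: on such trials
#' neither accumulator ever reaches threshold.  Reported as a diagnostic for
#' the un-normalized likelihood convention.
#'
#' @param params An [lba_params()] object.
#' @return A probability.
#' @export
all_negative_mass <- function(params) {
  v <- effective_drifts(params)
  stats::pnorm(-v[["target"]] / params$s_correct) *
    stats::pnorm(-v[["foil"]] / params$s_error)
}

#' Probability of a correct response
#'
#' Integral of the defective target density over all response times, divided
#' by the total response mass (one minus the probability that both drifts
#' are non-positive), so the value is the probability of a correct response
#' conditional on a response occurring.
#'
#' @param params An [lba_params()] object.
#' @param rel_tol Relative tolerance passed to the adaptive quadrature.
#' @return A probability in `[0, 1]`.
#' @export
choice_prob <- function(params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "lba_params"))
  mass_target <- defective_mass(params, "target", rel_tol)
  total <- 1 - all_negative_mass(params)
  min(max(mass_target / total, 0), 1)
}

# Total mass of one defective density by adaptive quadrature.  The crossing
# time has a heavy (1/t^2) tail from near-zero positive drift draws, so the
# bulk (up to a characteristic slow crossing) and the tail (to infinity,
# handled by integrate()'s transformation) are integrated separately.
defective_mass <- function(params, response, rel_tol = 1e-10) {
  split <- params$t0 + 4 * params$b /
    max(min(effective_drifts(params)), 0.25)
  bulk <- stats::integrate(function(t) defective_pdf(t, response, params),
                           lower = params$t0, upper = split,
                           rel.tol = rel_tol, subdivisions = 1000L)$value
  tail <- stats::integrate(function(t) defective_pdf(t, response, params),
                           lower = split, upper = Inf,
                           rel.tol = rel_tol, subdivisions = 1000L)$value
  bulk + tail
}

#' Trial log-likelihood under the LBA
#'
#' Natural log of the defective density at the observed response time, with
#' the density floored at `1e-300` so the log never underflows to `-Inf`
#' for admissible times; times at or below `t0` do return `-Inf`.
#'
#' @param rt_s Response time(s), seconds.
#' @param response Response label(s), `"target"` or `"foil"`.
#' @param params An [lba_params()] object.
#' @return Log densities; `-Inf` where `rt_s <= t0`.
#' @export
trial_loglik <- function(rt_s, response, params) {
  d <- defective_pdf(rt_s, response, params)
  out <- log(pmax(d, DENSITY_FLOOR))
  out[rt_s <= params$t0] <- -Inf
  out
}

# Flat, allocation-lean defective log-density used in the sampler's inner
# loop: all arguments are vectors of the same length n (one entry per
# trial), `correct` is logical.  Returns the summed log-likelihood.
# Mathematically identical to sum(trial_loglik(...)) with cell-resolved
# parameters; kept separate so the per-iteration cost stays in vectorized
# pnorm/dnorm calls.
lba_sumloglik_flat <- function(rt, correct, A, bthr, v_t, v_f, s_t, s_f, t0) {
  tau <- rt - t0
  if (any(tau <= 0)) return(-Inf)
  ts_t <- tau * s_t
  ts_f <- tau * s_f
  z1t <- (bthr - A - tau * v_t) / ts_t
  z2t <- (bthr - tau * v_t) / ts_t
  z1f <- (bthr - A - tau * v_f) / ts_f
  z2f <- (bthr - tau * v_f) / ts_f
  p_z1t <- stats::pnorm(z1t); p_z2t <- stats::pnorm(z2t)
  p_z1f <- stats::pnorm(z1f); p_z2f <- stats::pnorm(z2f)
  d_z1t <- stats::dnorm(z1t); d_z2t <- stats::dnorm(z2t)
  d_z1f <- stats::dnorm(z1f); d_z2f <- stats::dnorm(z2f)
  pdf_t <- pmax((v_t * (p_z2t - p_z1t) + s_t * (d_z1t - d_z2t)) / A, 0)
  pdf_f <- pmax((v_f * (p_z2f - p_z1f) + s_f * (d_z1f - d_z2f)) / A, 0)
  cdf_t <- pmin(pmax(1 + ((bthr - A - tau * v_t) / A) * p_z1t -
                       ((bthr - tau * v_t) / A) * p_z2t +
                       (ts_t / A) * (d_z1t - d_z2t), 0), 1)
  cdf_f <- pmin(pmax(1 + ((bthr - A - tau * v_f) / A) * p_z1f -
                       ((bthr - tau * v_f) / A) * p_z2f +
                       (ts_f / A) * (d_z1f - d_z2f), 0), 1)
  dens <- ifelse(correct, pdf_t * (1 - cdf_f), pdf_f * (1 - cdf_t))
  sum(log(pmax(dens, DENSITY_FLOOR)))
}

#' Map additive urgency to the equivalent linearly collapsing threshold
#'
#' For a ballistic accumulator, adding a constant `u` to every drift rate
#' while keeping the threshold fixed at `b` is exactly equivalent to keeping
#' the drifts and letting the threshold collapse linearly as `b - u * tau`:
#' for a shared start point `k` and drift draw `d` with `d + u > 0`, the
#' crossing time `(b - k) / (d + u)` solves both `k + (d + u) tau = b` and
#' `k + d tau = b - u tau`.  This function returns the drift-shifted static
#' form, the collapsing-threshold slope, and evaluators for the crossing
#' time under each form so the equivalence can be checked draw by draw.
#'
#' @param params An [lba_params()] object with urgency component `u`.
#' @return A list with elements `static` (an [lba_params()] with the urgency
#'   folded into the drifts), `slope` (the collapse rate `u`, evidence units
#'   per second), and functions `crossing_static(start, drift)` /
#'   `crossing_collapse(start, drift)` giving the crossing time of one
#'   accumulator under each parametrization for shared draws (`drift` is the
#'   stimulus drift, without urgency; `Inf` when the accumulator never
#'   crosses).
#' @export
collapse_equivalent <- function(params) {
  stopifnot(inherits(params, "lba_params"))
  u <- params$urgency
  b <- params$b
  static <- lba_params(A = params$A, B = params$B,
                       v_correct = params$v_correct + u,
                       delta_v = params$delta_v,
                       s_error = params$s_error, t0 = params$t0,
                       urgency = 0)
  crossing_static <- function(start, drift) {
    eff <- drift + u
    ifelse(eff > 0, (b - start) / eff, Inf)
  }
  crossing_collapse <- function(start, drift) {
    # threshold b - u * tau; crossing when start + drift * tau = b - u * tau
    eff <- drift + u
    ifelse(eff > 0, (b - start) / eff, Inf)
  }
  list(static = static, slope = u,
       crossing_static = crossing_static,
       crossing_collapse = crossing_collapse)
}
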