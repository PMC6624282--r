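# Model variants, parameter layouts, prior and hyperprior densities.

test_that("parameter counts and chain counts follow the sharing rules", {
  cells6 <- design_cells()
  expect_equal(nrow(cells6), 6)
  expect_setequal(cells6$cell,
                  c("Neutral:Baseline", "Neutral:Begin", "Neutral:End",
                    "Warm:Baseline", "Warm:Begin", "Warm:End"))
  m <- build_model("both", cells6)
  expect_equal(m$n_params, 16)  # 4 shared + 6 drifts + 6 thresholds
  expect_equal(m$D, 48)
  m1 <- build_model("threshold_only", "Neutral:Baseline")
  expect_equal(m1$n_params, 6)
  expect_equal(m1$D, 18)
  # hand counts for all variants x cell subsets
  for (variant in c("rate_only", "threshold_only", "both")) {
    for (nc in c(1, 2, 6)) {
      cl <- cells6$cell[seq_len(nc)]
      mm <- build_model(variant, cl)
      n_free <- if (variant == "both") 2L else 1L
      expect_equal(mm$n_params, (6 - n_free) + n_free * nc)
      expect_equal(mm$D, 3 * mm$n_params)
      expect_setequal(mm$shared[mm$shared %in%
                                  c("A", "s_error", "t0", "delta_v")],
                      c("A", "s_error", "t0", "delta_v"))
    }
  }
  expect_error(build_model("both", character(0)), "nonempty")
  expect_error(build_model("fanciest"), "arg")
})

test_that("cell resolution broadcasts shared parameters", {
  m <- build_model("threshold_only", c("Warm:Baseline", "Warm:End"))
  theta <- c(2.5, 1.2, 0.9, 0.5, 0.2, 0.8, 0.6)
  names(theta) <- m$layout$name
  p1 <- cell_params(theta, m, "Warm:Baseline")
  p2 <- cell_params(theta, m, "Warm:End")
  expect_equal(p1$A, p2$A)
  expect_equal(p1$t0, p2$t0)
  expect_equal(p1$v_correct, p2$v_correct)
  expect_false(p1$B == p2$B)
})

test_that("participant prior: bound violations, flatness limit, quadrature oracle", {
  m <- build_model("threshold_only", "Neutral:Baseline")
  pr <- prior_spec()
  mid <- c(v_correct = 3, delta_v = 1, s_error = 1, A = 0.5, t0 = 0.2,
           B = 0.8)
  theta <- mid[m$layout$base]
  names(theta) <- m$layout$name
  phi <- list(mean = rep(1, 6), sd = rep(1, 6))
  expect_true(is.finite(log_prior_participant(theta, phi, m, pr)))
  bad <- theta
  bad[m$layout$base == "t0"] <- 0.6   # outside U(0.01, 0.5)
  expect_identical(log_prior_participant(bad, phi, m, pr), -Inf)
  # hyperSD -> Inf: truncated normal flattens to the uniform
  big <- list(mean = rep(2, 6), sd = rep(1e8, 6))
  theta2 <- theta
  theta2[1] <- theta2[1] + 0.5
  ratio <- log_prior_participant(theta, big, m, pr) -
    log_prior_participant(theta2, big, m, pr)
  expect_equal(ratio, 0, tolerance = 1e-6)
  # quadrature-normalized truncated-normal oracle
  phi3 <- list(mean = c(2, 1.5, 1, 0.4, 0.25, 1), sd = c(1, 2, 0.5, 0.3, 0.1, 0.7))
  b <- thermolba:::participant_bounds(m, pr)
  oracle <- 0
  for (k in seq_len(6)) {
    Z <- integrate(function(x) dnorm(x, phi3$mean[k], phi3$sd[k]),
                   b[k, "lower"], b[k, "upper"], rel.tol = 1e-13)$value
    oracle <- oracle + dnorm(theta[k], phi3$mean[k], phi3$sd[k],
                             log = TRUE) - log(Z)
  }
  expect_equal(log_prior_participant(theta, phi3, m, pr), unname(oracle),
               tolerance = 1e-10)
})

test_that("hyperprior: exponential closed form, bounds, additivity", {
  m <- build_model("threshold_only", "Neutral:Baseline")
  pr <- prior_spec()
  b <- thermolba:::hypermean_bounds(m, pr)
  mid <- (b[, "lower"] + b[, "upper"]) / 2
  # Gamma(1,1) = Exp(1): each hyperSD = 1 contributes log density -1
  phi <- list(mean = mid, sd = rep(1, 6))
  expected <- sum(-log(b[, "upper"] - b[, "lower"])) + 6 * (-1)
  expect_equal(log_hyperprior(phi, m, pr), expected, tolerance = 1e-12)
  # hypermean outside its printed support
  phi_bad <- phi
  phi_bad$mean[m$layout$base == "v_correct"] <- 12  # outside U(0, 10)
  expect_identical(log_hyperprior(phi_bad, m, pr), -Inf)
  phi_bad2 <- phi
  phi_bad2$sd[2] <- -0.1
  expect_identical(log_hyperprior(phi_bad2, m, pr), -Inf)
})

test_that("prior supports are closed under sampling", {
  # draws from the prior never evaluate to -Inf
  m <- build_model("both", c("Neutral:Baseline", "Warm:End"))
  pr <- prior_spec()
  b <- thermolba:::participant_bounds(m, pr)
  hb <- thermolba:::hypermean_bounds(m, pr)
  set.seed(314)
  for (k in 1:50) {
    phi <- list(mean = runif(m$n_params, hb[, "lower"], hb[, "upper"]),
                sd = rgamma(m$n_params, 1, 1) + 1e-8)
    theta <- runif(m$n_params, b[, "lower"], b[, "upper"])
    names(theta) <- m$layout$name
    expect_true(is.finite(log_hyperprior(phi, m, pr)))
    expect_true(is.finite(log_prior_participant(theta, phi, m, pr)))
  }
})

test_that("dataset log likelihood: empty data, additivity, loop oracle", {
  m <- build_model("threshold_only", c("Warm:Baseline", "Warm:End"))
  fx <- fixture_small_study(n_participants = 2, n_trials = 25)
  ch <- fx$choice
  theta_all <- lapply(unique(ch$participant_id), function(id) {
    th <- c(3, 1.5, 1, 0.5, 0.2, 0.9, 0.7)
    names(th) <- m$layout$name
    th
  })
  names(theta_all) <- unique(ch$participant_id)
  expect_equal(dataset_loglik(ch[0, ], theta_all, m), 0)
  full <- dataset_loglik(ch, theta_all, m)
  half1 <- dataset_loglik(ch[1:40, ], theta_all, m)
  half2 <- dataset_loglik(ch[-(1:40), ], theta_all, m)
  expect_equal(full, half1 + half2, tolerance = 1e-10)
  # naive per-trial loop oracle
  oracle <- 0
  for (r in seq_len(nrow(ch))) {
    p <- cell_params(theta_all[[ch$participant_id[r]]], m, ch$cell[r])
    oracle <- oracle + trial_loglik(ch$rt_s[r],
                                    if (ch$correct[r]) "target" else "foil",
                                    p)
  }
  expect_equal(full, oracle, tolerance = 1e-9)
  expect_error(dataset_loglik(ch, theta_all["p01"], m), "no parameters")
})

test_that("restricted variants are nested in the full model", {
  # a 'both' parameter vector with equal-across-cell drifts reproduces the
  # threshold_only likelihood, and vice versa
  cells <- c("Warm:Baseline", "Warm:End")
  m_both <- build_model("both", cells)
  m_thr <- build_model("threshold_only", cells)
  fx <- fixture_small_study(n_participants = 2, n_trials = 20)
  ch <- fx$choice
  ids <- unique(ch$participant_id)
  th_thr <- c(3, 1.5, 1, 0.5, 0.2, 0.9, 0.7)
  theta_thr <- lapply(ids, function(id) {
    names(th_thr) <- m_thr$layout$name; th_thr })
  names(theta_thr) <- ids
  # same cell-level parameters expressed in the 'both' layout
  theta_both <- lapply(ids, function(id) {
    th <- numeric(m_both$n_params)
    names(th) <- m_both$layout$name
    for (cl in cells) {
      p <- cell_params(theta_thr[[id]], m_thr, cl)
      th[paste("v_correct", cl, sep = "|")] <- p$v_correct
      th[paste("B", cl, sep = "|")] <- p$B
      th["A"] <- p$A; th["delta_v"] <- p$delta_v
      th["s_error"] <- p$s_error; th["t0"] <- p$t0
    }
    th
  })
  names(theta_both) <- ids
  expect_equal(dataset_loglik(ch, theta_both, m_both),
               dataset_loglik(ch, theta_thr, m_thr), tolerance = 1e-10)
})

test_that("fast participant likelihood matches the reference path", {
  m <- build_model("both", c("Warm:Baseline", "Warm:End"))
  fx <- fixture_small_study(n_participants = 2, n_trials = 30)
  ch <- fx$choice
  id <- unique(ch$participant_id)[1]
  tr <- ch[ch$participant_id == id, ]
  pdat <- thermolba:::participant_data(tr, m)[[1]]
  theta <- c(3, 1.4, 1.1, 0.6, 0.22, 3.1, 2.9, 0.9, 0.75)
  names(theta) <- m$layout$name
  fast <- thermolba:::participant_loglik_fast(theta, pdat, m)
  slow <- dataset_loglik(tr, setNames(list(theta), id), m)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("compiled and vectorized likelihood paths agree", {
  m <- build_model("both", c("Warm:Baseline", "Warm:End"))
  fx <- fixture_small_study(n_participants = 2, n_trials = 30)
  tr <- fx$choice[fx$choice$participant_id == "p01", ]
  pdat <- thermolba:::participant_data(tr, m)[[1]]
  set.seed(55)
  pb <- thermolba:::participant_bounds(m)
  theta_mat <- t(replicate(5, runif(m$n_params, pb[, "lower"],
                                    pmin(pb[, "upper"], 5))))
  cpp <- thermolba:::lba_loglik_chains(theta_mat, pdat$cellidx,
                                       pdat$rt, pdat$correct)
  vec <- thermolba:::participant_loglik_matrix(theta_mat, pdat, m)
  expect_equal(cpp, vec, tolerance = 1e-10)
  one <- vapply(seq_len(5), function(i)
    thermolba:::participant_loglik_fast(theta_mat[i, ], pdat, m),
    numeric(1))
  expect_equal(cpp, one, tolerance = 1e-10)
})
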