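test_that("profile through the MLE reproduces the unconstrained optimum", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 0.5), 150, seed = 23)
  fit <- fit_mle(s)
  mle <- fit$theta_hat[["sigma_eta"]]
  grid <- sort(c(mle, seq(0.2, 1, length.out = 9)))
  prof <- profile_likelihood(s, "sigma_eta", grid)
  expect_equal(max(prof$profile_loglik), fit$loglik_max, tolerance = 1e-6)
  # invariant: no profiled point exceeds the unconstrained optimum
  expect_true(all(prof$profile_loglik <= prof$loglik_max + 1e-6))
  # the MLE lies inside the chi-square profile interval
  expect_true(mle >= min(prof$profile_ci) && mle <= max(prof$profile_ci))
})

test_that("multi-start profile points dominate single-start refits", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 0.05), 100, seed = 37)
  grid <- c(0.02, 0.08, 0.15)
  prof <- profile_likelihood(s, "sigma_eps", grid)
  one_start <- default_starts(s)[2, , drop = FALSE]
  for (i in seq_along(grid)) {
    single <- fit_mle(s, fixed = c(sigma_eps = grid[i]), starts = one_start)
    expect_gte(prof$profile_loglik[i], single$loglik_max - 1e-8)
  }
})

test_that("flat-segment and mode counting behave on constructed profiles", {
  flat <- ssmcheck:::.flat_segments
  modes <- ssmcheck:::.count_local_maxima

  # a 10-point profile flat in the middle
  prof <- c(0, 1, 2, 2.01, 2.02, 2.01, 2.02, 3, 4, 5)
  segs <- flat(prof, tol = 0.05)
  expect_true(length(segs) >= 1)
  expect_true(any(vapply(segs, function(s) s[2] - s[1] + 1L, integer(1)) >= 5))

  expect_identical(modes(c(0, 1, 2, 3, 2, 1, 0), tol = 0.1), 1L)
  expect_identical(modes(c(0, 2, 0.5, 3, 1), tol = 0.1), 2L)
  # sub-prominence jitter does not create modes
  expect_identical(modes(c(0, 1, 2, 2.001, 2, 2.002, 2, 1), tol = 0.1), 1L)
})

test_that("a 1x1 likelihood surface at the MLE equals the optimum", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 0.5), 120, seed = 41)
  fit <- fit_mle(s)
  surf <- likelihood_surface(s, "sigma_eta", "sigma_eps",
                             fit$theta_hat[["sigma_eta"]],
                             fit$theta_hat[["sigma_eps"]])
  expect_equal(surf$loglik[1, 1], fit$loglik_max, tolerance = 1e-6)
})

test_that("axis-wise surface maxima reproduce the one-dimensional profile", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 0.3), 100, seed = 53)
  grid_a <- c(0.15, 0.3, 0.45)
  grid_b <- seq(0.02, 0.4, length.out = 8)
  surf <- likelihood_surface(s, "sigma_eta", "sigma_eps", grid_a, grid_b)
  prof <- profile_likelihood(s, "sigma_eta", grid_a)
  # profiling sigma_eps out by a dense-enough grid approximates re-optimization
  expect_equal(apply(surf$loglik, 1, max), prof$profile_loglik,
               tolerance = 0.05)
})

test_that("low-process-noise surfaces show a likelihood ridge", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 0.02), 100, seed = 61)
  g_eta <- seq(0.005, 0.08, length.out = 6)
  g_eps <- seq(0.05, 0.13, length.out = 6)
  surf <- likelihood_surface(s, "sigma_eta", "sigma_eps", g_eta, g_eps)
  # near-constant log-likelihood along the best trade-off curve: the spread
  # of row maxima is tiny compared to the spread across the whole surface
  row_max <- apply(surf$loglik, 1, max)
  expect_lt(diff(range(row_max)), 0.1 * diff(range(surf$loglik)))
})

test_that("parametric bootstrap intervals behave at the edges", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 1), 100, seed = 71)
  fit <- fit_mle(s)
  bt <- parametric_bootstrap(fit, B = 1, seed = 5)
  expect_equal(bt$ci[, "lower"], bt$ci[, "upper"]) # degenerate at B = 1
  expect_equal(nrow(bt$theta), 1L)

  bt9 <- parametric_bootstrap(fit, B = 9, seed = 5)
  expect_true(all(bt9$ci[, "lower"] <= bt9$ci[, "upper"]))
  expect_equal(ncol(bt9$state_ci), 2L)
  expect_equal(nrow(bt9$state_ci), s$n)
})

test_that("bootstrap intervals cover truth in a high-signal scenario", {
  # scaled-down coverage simulation: 25 outer truths x B = 59
  p <- ssm_params(sigma_eps = 0.1, rho = 0.7, sigma_eta = 1)
  hits <- logical(25)
  for (i in seq_along(hits)) {
    s <- simulate_ssm(p, 100, seed = 9000 + i)
    fit <- fit_mle(s)
    bt <- suppressWarnings(
      parametric_bootstrap(fit, B = 59, seed = 10000 + 59 * i))
    hits[i] <- bt$ci["sigma_eta", "lower"] <= 1 &&
      bt$ci["sigma_eta", "upper"] >= 1
  }
  # percentile intervals of a skewed, boundary-prone estimator undercover
  # a nominal 95%; measured coverage at this size is ~0.76-0.82
  expect_gte(mean(hits), 0.70)
  expect_lte(mean(hits), 1.00)
})

test_that("bootstrap intervals at low process noise are wide and touch the boundary", {
  s <- simulate_ssm(ssm_params(0.1, 0.7, 0.02), 100, seed = 303)
  fit <- fit_mle(s)
  bt <- parametric_bootstrap(fit, B = 39, seed = 11)
  thr <- 1e-2 * sd(s$y)
  boundary_frac <- mean(bt$theta[, "sigma_eps"] < thr |
                          bt$theta[, "sigma_eta"] < thr)
  expect_gt(boundary_frac, 0.2)
  # interval spans a large part of the parameter scale relative to truth
  expect_gt(bt$ci["sigma_eta", "upper"] / max(bt$ci["sigma_eta", "lower"], 1e-6), 3)
})
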