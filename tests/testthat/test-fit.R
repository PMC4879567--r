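test_that("a fully constrained fit returns the fixed values and their likelihood", {
  p <- ssm_params(0.1, 0.7, 0.2)
  s <- simulate_ssm(p, 80, seed = 31)
  fx <- c(sigma_eps = 0.1, rho = 0.7, sigma_eta = 0.2)
  fit <- fit_mle(s, fixed = fx)
  expect_equal(fit$theta_hat, fx)
  expect_equal(fit$loglik_max, kalman_filter_loglik(p, s)$loglik,
               tolerance = 1e-10)
  expect_true(all(fit$fixed_mask))
  expect_equal(unname(fit$se), c(0, 0, 0))
})

test_that("estimates are consistent at high signal-to-noise", {
  p <- ssm_params(sigma_eps = 0.1, rho = 0.7, sigma_eta = 1)
  s <- simulate_ssm(p, 10000, seed = 99)
  fit <- fit_mle(s)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta_hat[["rho"]] - 0.7), 0.05)
  expect_lt(abs(fit$theta_hat[["sigma_eta"]] - 1), 0.05)
  # sigma_eps is weakly identified at this noise ratio (sampling SD ~ 0.075
  # even at this length); a 3-SD bound is the attainable pointwise check
  expect_lt(abs(fit$theta_hat[["sigma_eps"]] - 0.1), 0.25)

  # coarse grid-search oracle: no grid point beats the optimizer
  grid <- expand.grid(sigma_eps = c(0.05, 0.1, 0.2),
                      rho = c(0.5, 0.7, 0.9),
                      sigma_eta = c(0.5, 1, 1.5))
  ll_grid <- apply(grid, 1, function(g)
    kalman_filter_loglik(ssm_params(g[1], g[2], g[3]), s)$loglik)
  expect_gte(fit$loglik_max, max(ll_grid) - 1e-6)
})

test_that("reported optimum is reproducible from the filter at theta_hat", {
  set.seed(505)
  for (i in 1:8) {
    pp <- ssm_params(0.1, 0.7, c(0.01, 0.05, 0.2, 1)[1 + (i %% 4)])
    s <- simulate_ssm(pp, 100, seed = 600 + i)
    fit <- fit_mle(s)
    th <- fit$theta_hat
    ll <- kalman_filter_loglik(ssm_params(th[["sigma_eps"]], th[["rho"]],
                                          th[["sigma_eta"]]), s)$loglik
    expect_equal(fit$loglik_max, ll, tolerance = 1e-8)
  }
})

test_that("adding starts never decreases the returned optimum", {
  p <- ssm_params(0.1, 0.7, 0.05)
  s <- simulate_ssm(p, 100, seed = 77)
  all_starts <- default_starts(s)
  fit1 <- fit_mle(s, starts = all_starts[1, , drop = FALSE])
  fit3 <- fit_mle(s, starts = all_starts)
  expect_gte(fit3$loglik_max, fit1$loglik_max - 1e-8)
})

test_that("interior screening returns the best non-boundary start solution", {
  # low process noise: the global optimum often has a boundary variance
  found <- FALSE
  for (seed in 201:230) {
    s <- simulate_ssm(ssm_params(0.1, 0.7, 0.02), 100, seed = seed)
    fit <- fit_mle(s)
    if (any(fit$boundary_flags) && any(!fit$start_boundary)) {
      fit_int <- fit_mle(s, interior_only = TRUE)
      expect_false(any(fit_int$boundary_flags))
      expect_lte(fit_int$loglik_max, fit$loglik_max + 1e-8)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("known-states fit matches the closed-form complete-data MLEs", {
  p <- ssm_params(0.3, 0.6, 0.5, x0 = 0)
  s <- simulate_ssm(p, 500, seed = 12)
  fit <- fit_known_states(s, s$x_true)
  x <- s$x_true
  prev <- c(0, x[-length(x)])
  rho_cf <- sum(prev * x) / sum(prev^2)
  sigma_eta_cf <- sqrt(mean((x - rho_cf * prev)^2))
  sigma_eps_cf <- sqrt(mean((s$y - x)^2))
  expect_equal(fit$theta_hat[["rho"]], rho_cf, tolerance = 1e-6)
  expect_equal(fit$theta_hat[["sigma_eta"]], sigma_eta_cf, tolerance = 1e-6)
  expect_equal(fit$theta_hat[["sigma_eps"]], sigma_eps_cf, tolerance = 1e-6)
})

test_that("observations equal to the states drive sigma_eps to the boundary", {
  p <- ssm_params(0.3, 0.6, 0.5, x0 = 0)
  s0 <- simulate_ssm(p, 200, seed = 14)
  s <- ssm_series(s0$x_true, x_true = s0$x_true) # y identical to x
  fit <- fit_known_states(s, s$x_true)
  expect_true(fit$boundary_flags[["sigma_eps"]])
  expect_lt(fit$theta_hat[["sigma_eps"]], 1e-2 * sd(s$y))
})

test_that("Wald interval arithmetic follows the normal quantile", {
  fake <- structure(list(
    theta_hat = c(sigma_eps = 0, rho = 0.5, sigma_eta = 1),
    se = c(sigma_eps = 1, rho = 0, sigma_eta = NA_real_)),
    class = "ssm_fit")
  ci <- wald_ci(fake, 0.95)
  expect_equal(unname(ci["sigma_eps", c("lower", "upper")]),
               c(-1.959964, 1.959964), tolerance = 1e-6)
  # zero SE degenerates to the point estimate
  expect_equal(unname(ci["rho", "lower"]), 0.5)
  expect_equal(unname(ci["rho", "upper"]), 0.5)
  # non-finite SE marks the interval unavailable
  expect_true(is.na(ci["sigma_eta", "lower"]))
})

test_that("Wald and profile intervals agree when the likelihood is near quadratic", {
  # long, well-identified series: the log-likelihood is locally quadratic,
  # so the chi-square profile cutoff and the Wald interval should coincide
  p <- ssm_params(sigma_eps = 0.5, rho = 0.6, sigma_eta = 1)
  s <- simulate_ssm(p, 3000, seed = 8)
  fit <- fit_mle(s)
  ci <- wald_ci(fit, 0.95)
  lo <- ci["rho", "lower"]; hi <- ci["rho", "upper"]
  grid <- seq(lo - 0.3 * (hi - lo), hi + 0.3 * (hi - lo), length.out = 41)
  prof <- profile_likelihood(s, "rho", grid)
  expect_lt(abs(min(prof$profile_ci) - lo), 0.15 * (hi - lo))
  expect_lt(abs(max(prof$profile_ci) - hi), 0.15 * (hi - lo))
})
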