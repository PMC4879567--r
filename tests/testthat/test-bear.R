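make_bear <- function(n_days = 342, seed = 1, ...) {
  cfg <- bear_sim_config(n_bears = 1, n_days = n_days, seed = seed, ...)
  simulate_bear_paths(cfg)
}

test_that("drift correction subtracts observed drift and propagates missingness", {
  b <- make_bear(60, seed = 2, missing_rate = 0)
  # zero drift observation: z equals the bear displacement
  b0 <- b; b0$s_u <- 0; b0$s_v <- 0
  z0 <- drift_correct(b0)
  expect_equal(z0$u$y, b$y_u)
  # drift equal to the displacement: z is identically zero
  bs <- b; bs$s_u <- b$y_u; bs$s_v <- b$y_v
  zs <- drift_correct(bs)
  expect_true(all(zs$u$y == 0) && all(zs$v$y == 0))
  # a single missing drift day makes only that day missing
  bm <- b; bm$s_u[10] <- NA
  zm <- drift_correct(bm)
  expect_true(is.na(zm$u$y[10]))
  expect_equal(sum(is.na(zm$u$y)), 1L)
  expect_false(anyNA(zm$v$y))

  expect_error(drift_correct(list(y_u = 1:5, y_v = 1:5, s_u = 1:4, s_v = 1:5)),
               "misaligned")
})

test_that("per-coordinate bear fits equal standalone univariate fits", {
  b <- make_bear(200, seed = 7)
  fit <- fit_bear(b, n_days = 200)
  z <- drift_correct(b)
  solo <- fit_mle(z$u, x0 = 0, x0_prior = "gaussian", sigma0 = 15)
  expect_equal(fit$fit_u$theta_hat, solo$theta_hat, tolerance = 1e-10)
  expect_equal(fit$fit_u$loglik_max, solo$loglik_max, tolerance = 1e-10)
})

test_that("bear parameters are recovered on long series", {
  b <- make_bear(20000, seed = 11, rho_u = 0.3, rho_v = 0.3,
                 sigma_q_u = 4, sigma_q_v = 4, sigma_h_u = 6, sigma_h_v = 6,
                 missing_rate = 0)
  fit <- fit_bear(b, n_days = 342)
  # the high-error regime (sigma_h > sigma_q, weak autocorrelation) keeps a
  # substantial sampling spread even at this length: rho_hat SD ~ 0.06,
  # SD estimates ~ 10% relative; bounds below are ~2.5 sampling SDs
  for (i in 1:2) {
    expect_lt(abs(fit$params$rho[i] - 0.3), 0.15)
    expect_lt(abs(fit$params$sigma_q[i] - 4) / 4, 0.25)
    expect_lt(abs(fit$params$sigma_h[i] - 6) / 6, 0.20)
  }
})

test_that("total voluntary displacement follows its definition", {
  expect_equal(total_voluntary_displacement(cbind(rep(0, 10), rep(0, 10))), 0)
  expect_equal(total_voluntary_displacement(cbind(rep(3, 10), rep(4, 10)),
                                            n = 10), 50)
  expect_error(total_voluntary_displacement(cbind(1:5, 1:5), n = 6),
               "exceeds")
})

test_that("d is invariant under a simultaneous sign flip of both coordinates", {
  b <- make_bear(120, seed = 13)
  fit <- fit_bear(b, n_days = 120)
  bf <- b
  for (cn in c("y_u", "y_v", "s_u", "s_v")) bf[[cn]] <- -bf[[cn]]
  fitf <- fit_bear(bf, n_days = 120)
  expect_equal(fitf$d, fit$d, tolerance = 1e-6)
})

test_that("pooled fit with a single bear matches the individual fit", {
  b <- make_bear(250, seed = 17)
  pooled <- fit_pooled(b)
  solo <- fit_bear(b, n_days = 250)
  expect_equal(pooled$u$sigma_h, solo$params$sigma_h[1], tolerance = 1e-3)
  expect_equal(pooled$u$per_bear$rho[1], solo$params$rho[1], tolerance = 1e-3)
  expect_equal(pooled$u$loglik, solo$fit_u$loglik_max, tolerance = 1e-4)
})

test_that("pooled log-likelihood is additive over bears at the optimum", {
  cfg <- bear_sim_config(n_bears = 3, n_days = 150, seed = 19)
  bears <- simulate_bear_paths(cfg)
  pooled <- fit_pooled(bears)
  ll <- 0
  for (i in 1:3) {
    z <- drift_correct(bears[bears$bear_id == i, ])
    pb <- pooled$u$per_bear
    p <- ssm_params(pooled$u$sigma_h, pb$rho[pb$bear_id == i],
                    pb$sigma_q[pb$bear_id == i],
                    x0 = 0, x0_prior = "gaussian", sigma0 = 15)
    ll <- ll + kalman_filter_loglik(p, z$u)$loglik
  }
  expect_equal(pooled$u$loglik, ll, tolerance = 1e-6)
})

test_that("pooling shrinks the spread of measurement-error estimates", {
  sh_ind <- c(); sh_pool <- c()
  for (r in 1:5) {
    cfg <- bear_sim_config(n_bears = 6, n_days = 150, seed = 23000 + r)
    bears <- simulate_bear_paths(cfg)
    pooled <- fit_pooled(bears)
    sh_pool <- c(sh_pool, pooled$u$sigma_h)
    ind <- sapply(1:6, function(i)
      fit_bear(bears[bears$bear_id == i, ], n_days = 150)$params$sigma_h[1])
    sh_ind <- c(sh_ind, ind)
  }
  expect_lt(sd(sh_pool), sd(sh_ind))
})

test_that("boundary bears track the corrected series and inflate the energy proxy", {
  st <- cached_study("bear_pool", function() {
    out <- NULL
    for (r in 1:6) {
      cfg <- bear_sim_config(seed = 60000 + 1000 * r)
      s <- run_bear_study(cfg)
      s$rep <- r
      out <- rbind(out, s)
    }
    out
  })
  b <- st$boundary_any
  expect_gt(sum(b), 0)
  expect_lt(mean(b), 0.5) # a minority of bears
  # directional bias: estimated d under boundary fits exceeds the truth-based d
  expect_gt(mean(st$d_hat[b] - st$d_true[b]), 0)
  # boundary bears sit high in the d distribution
  expect_gt(mean(st$d_hat[b]), mean(st$d_hat[!b]))
})

test_that("boundary fits produce smoothed states glued to the observations", {
  found_b <- FALSE; found_i <- FALSE
  track_b <- c(); track_i <- c()
  for (seed in 71:90) {
    b <- make_bear(342, seed = seed)
    fit <- fit_bear(b)
    z <- drift_correct(b)
    obs <- !is.na(z$u$y)
    track <- mean(abs(fit$c_hat[obs, "u"] - z$u$y[obs]))
    if (fit$params$boundary_sigma_h[1]) {
      track_b <- c(track_b, track); found_b <- TRUE
    } else {
      track_i <- c(track_i, track); found_i <- TRUE
    }
    if (found_b && found_i && length(track_b) + length(track_i) >= 12) break
  }
  expect_true(found_b && found_i)
  expect_lt(mean(track_b), mean(track_i))
})
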