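test_that("state RMSE follows its definition", {
  expect_identical(state_rmse(1:5, 1:5), 0)
  expect_equal(state_rmse(rep(2.5, 10), rep(0, 10)), 2.5)
  expect_equal(state_rmse(c(3, 4), c(0, 0)), sqrt(12.5), tolerance = 1e-12)
  expect_error(state_rmse(1:3, 1:4), "equal length")
})

test_that("a true-parameters-only replicate has rmse_hat equal to rmse_true", {
  cfg <- study_config(fit_free = FALSE, fit_fixed_eps = FALSE)
  r <- run_replicate(0.1, seed = 5, config = cfg)
  expect_equal(r$rmse_hat, r$rmse_true)
})

test_that("replicate RMSEs are reproducible by the dense smoother oracle", {
  cfg <- study_config(fit_fixed_eps = FALSE)
  r <- run_replicate(0.2, seed = 42, config = cfg)
  sim <- simulate_ssm(ssm_params(0.1, 0.7, 0.2), 100, seed = 42)
  p_true <- ssm_params(0.1, 0.7, 0.2)
  p_hat <- ssm_params(r$est_sigma_eps, r$est_rho, r$est_sigma_eta)
  expect_equal(r$rmse_true,
               state_rmse(oracle_smooth(p_true, sim$y), sim$x_true),
               tolerance = 1e-8)
  expect_equal(r$rmse_hat,
               state_rmse(oracle_smooth(p_hat, sim$y), sim$x_true),
               tolerance = 1e-8)
})

test_that("mini-studies are deterministic and correctly shaped", {
  cfg <- study_config(sigma_eta_grid = c(0.05, 1), n_replicates = 5,
                      base_seed = 900, fit_fixed_eps = TRUE)
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(a$replicates, b$replicates)
  expect_equal(nrow(a$replicates), 10L)
  expect_equal(as.vector(table(a$replicates$sigma_eta)), c(5L, 5L))
})

test_that("exceedance proportion counts ratio threshold crossings", {
  reps <- data.frame(sigma_eta = rep(0.1, 4), rmse_true = rep(1, 4),
                     rmse_hat = c(1.0, 1.4, 1.6, 2.0),
                     rmse_hat_fixed = NA_real_)
  expect_equal(proportion_exceeding(reps, factor = 1.5), 50)
  reps$rmse_hat <- reps$rmse_true
  expect_equal(proportion_exceeding(reps, factor = 1.5), 0)
  expect_error(proportion_exceeding(reps[0, ]), "empty")
})

test_that("bimodality check finds two-mode mixtures and ignores degenerate samples", {
  set.seed(61)
  mix <- c(rnorm(150, 0, 0.004), rnorm(150, 0.1, 0.01))
  bc <- bimodality_check(mix)
  expect_true(bc$bimodal)
  expect_true(any(abs(bc$modes) < 0.02))
  expect_false(bimodality_check(rep(0.3, 50))$bimodal)
  expect_false(bimodality_check(rnorm(300))$bimodal)
})

test_that("study summaries report boundary proportions from constructed input", {
  reps <- data.frame(
    sigma_eta = 0.05, n = 100, rho = 0.7, sigma_eps = 0.1,
    seed = 1:20, rmse_true = 0.05, rmse_hat = 0.06,
    rmse_hat_fixed = NA_real_,
    est_sigma_eps = rep(c(0.0001, 0.1), each = 10),
    est_rho = rep(c(0.01, 0.7), each = 10),
    est_sigma_eta = 0.05,
    est_rho_fixed = NA_real_, est_sigma_eta_fixed = NA_real_,
    converged = TRUE, converged_fixed = NA,
    boundary_sigma_eps = rep(c(TRUE, FALSE), each = 10),
    boundary_sigma_eta = FALSE, boundary_sigma_eta_fixed = NA,
    loglik_free = 0, loglik_fixed = NA_real_)
  st <- structure(list(config = study_config(), replicates = reps,
                       n_failed = c(free = 0, fixed = 0)),
                  class = "ssm_study")
  sm <- summarize_study(st)
  expect_equal(sm$prop_boundary_eps, 0.5)
  expect_equal(sm$sigma_eta_median, 0.05)
  expect_false(sm$sigma_eta_bimodal) # constant estimates carry no flags
})

test_that("state error under estimated parameters dominates in aggregate and shrinks with process noise", {
  st <- cached_study("mini", function()
    run_study(study_config(sigma_eta_grid = c(0.01, 1), n_replicates = 60,
                           base_seed = 4000, fit_fixed_eps = TRUE)))
  reps <- st$replicates
  for (g in split(reps, reps$sigma_eta)) {
    expect_gte(mean(g$rmse_hat), mean(g$rmse_true))
  }
  by_scen <- proportion_exceeding(st, 1.5, "free", by_scenario = TRUE)
  expect_lt(by_scen$percent[by_scen$sigma_eta == 1],
            by_scen$percent[by_scen$sigma_eta == 0.01])
})

test_that("fixing the measurement error reduces parameter bias in aggregate", {
  st <- cached_study("mini", function()
    run_study(study_config(sigma_eta_grid = c(0.01, 1), n_replicates = 60,
                           base_seed = 4000, fit_fixed_eps = TRUE)))
  reps <- st$replicates
  bias_free <- mean(abs(reps$est_rho - reps$rho)) +
    mean(abs(reps$est_sigma_eta - reps$sigma_eta))
  bias_fixed <- mean(abs(reps$est_rho_fixed - reps$rho)) +
    mean(abs(reps$est_sigma_eta_fixed - reps$sigma_eta))
  expect_lt(bias_fixed, bias_free)
})

test_that("longer series improve aggregate parameter recovery", {
  cfg100 <- study_config(sigma_eta_grid = 0.05, n_replicates = 40,
                         n = 100, base_seed = 7000)
  cfg500 <- study_config(sigma_eta_grid = 0.05, n_replicates = 40,
                         n = 500, base_seed = 7000)
  agg_rmse <- function(st) {
    r <- st$replicates
    sqrt(mean((r$est_rho - r$rho)^2)) +
      sqrt(mean((r$est_sigma_eta - r$sigma_eta)^2)) +
      sqrt(mean((r$est_sigma_eps - r$sigma_eps)^2))
  }
  expect_lt(agg_rmse(run_study(cfg500)), agg_rmse(run_study(cfg100)))
})
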