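# Independent brute-force oracles: the joint distribution of (x, y) is
# assembled element-wise from the model's closed-form covariances, and all
# conditional quantities come from dense linear algebra. No Kalman
# recursions anywhere in this file.

# joint mean/covariance of states x_1..x_n and observations y_1..y_n
oracle_joint <- function(params, n) {
  rho <- params$rho
  q <- params$sigma_eta^2
  p0 <- if (params$x0_prior == "gaussian") params$sigma0^2 else 0
  mean_x <- params$x0 * rho^(seq_len(n))
  Sxx <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      j <- seq_len(min(s, t))
      Sxx[s, t] <- p0 * rho^(s + t) + q * sum(rho^(s - j) * rho^(t - j))
    }
  }
  Syy <- Sxx + diag(params$sigma_eps^2, n)
  list(mean_x = mean_x, mean_y = mean_x, Sxx = Sxx, Syy = Syy, Sxy = Sxx)
}

oracle_logdmvnorm <- function(x, mu, S) {
  L <- chol(S)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# marginal log-likelihood of the observed entries of y
oracle_loglik <- function(params, y) {
  n <- length(y)
  obs <- which(!is.na(y))
  if (length(obs) == 0L) return(0)
  j <- oracle_joint(params, n)
  oracle_logdmvnorm(y[obs], j$mean_y[obs], j$Syy[obs, obs, drop = FALSE])
}

# smoothed state means E[x_t | observed y] by dense Gaussian conditioning
oracle_smooth <- function(params, y) {
  n <- length(y)
  obs <- which(!is.na(y))
  j <- oracle_joint(params, n)
  if (length(obs) == 0L) return(j$mean_x)
  j$mean_x + j$Sxy[, obs, drop = FALSE] %*%
    solve(j$Syy[obs, obs, drop = FALSE], y[obs] - j$mean_y[obs])
}

# random stationary parameter draw for property tests
random_params <- function(gaussian_x0 = FALSE) {
  ssm_params(sigma_eps = stats::runif(1, 0.05, 2),
             rho = stats::runif(1, -0.9, 0.95),
             sigma_eta = stats::runif(1, 0.05, 2),
             x0 = stats::rnorm(1, 0, 0.5),
             x0_prior = if (gaussian_x0) "gaussian" else "known",
             sigma0 = if (gaussian_x0) stats::runif(1, 0.2, 2) else NULL)
}

# a small cache for study objects shared across test files
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, maker) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, maker(), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}
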