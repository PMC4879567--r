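#' Autocovariance function of the stationary state-space model
#'
#' For `|rho| < 1` the observation process is stationary with
#' `gamma(0) = sigma_eta^2 / (1 - rho^2) + sigma_eps^2` and
#' `gamma(k) = rho^k * sigma_eta^2 / (1 - rho^2)` for `k >= 1`.
#'
#' @param params An [ssm_params()]; `|rho| < 1` required.
#' @param max_lag Largest lag to return.
#' @return Named numeric vector of autocovariances at lags `0..max_lag`.
#' @export
ssm_autocovariance <- function(params, max_lag = 10) {
  stopifnot(inherits(params, "ssm_params"))
  if (abs(params$rho) >= 1)
    stop("non-stationary: |rho| must be < 1", call. = FALSE)
  v_x <- params$sigma_eta^2 / (1 - params$rho^2)
  k <- 0:max_lag
  g <- params$rho^k * v_x
  g[1] <- g[1] + params$sigma_eps^2
  stats::setNames(g, paste0("lag", k))
}

#' Map the state-space model to its observationally equivalent ARMA(1,1)
#'
#' The differenced process `w_t = y_t - rho * y_{t-1}` is MA(1), so `y`
#' is ARMA(1,1) with `phi = rho` and `(theta_ma, sigma_e)` solving the MA(1)
#' moment equations
#' `(1 + theta^2) * sigma_e^2 = sigma_eta^2 + (1 + rho^2) * sigma_eps^2` and
#' `theta * sigma_e^2 = -rho * sigma_eps^2`,
#' with the invertible root (`|theta_ma| <= 1`). The mapped ARMA process
#' reproduces the state-space autocovariance function exactly. When the
#' measurement error dominates the process noise, `theta_ma` approaches
#' `-phi` — the AR and MA roots nearly cancel, so the model is close to
#' observationally indistinguishable from white noise and the parameters
#' become redundant.
#'
#' @inheritParams ssm_autocovariance
#' @return List of class `arma_params`: `phi`, `theta_ma`, `sigma_e`.
#' @export
ssm_to_arma <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  if (abs(params$rho) >= 1)
    stop("non-stationary: |rho| must be < 1", call. = FALSE)
  rho <- params$rho
  g0 <- params$sigma_eta^2 + (1 + rho^2) * params$sigma_eps^2
  g1 <- -rho * params$sigma_eps^2
  if (g0 <= 0) {
    # fully degenerate model (both noise terms zero)
    return(structure(list(phi = rho, theta_ma = 0, sigma_e = 0),
                     class = "arma_params"))
  }
  r <- g1 / g0
  if (r == 0) {
    theta <- 0
    sigma_e2 <- g0
  } else {
    # invertible root of theta / (1 + theta^2) = r; |r| <= 1/2 always.
    # 2r / (1 + sqrt(...)) is the cancellation-free form of the quadratic
    # root, and one Newton step removes the last bits of rounding error
    theta <- 2 * r / (1 + sqrt(1 - 4 * r^2))
    for (it in 1:2) {
      f <- theta / (1 + theta^2) - r
      fp <- (1 - theta^2) / (1 + theta^2)^2
      if (fp != 0) theta <- theta - f / fp
    }
    sigma_e2 <- g1 / theta
  }
  structure(list(phi = rho, theta_ma = theta, sigma_e = sqrt(sigma_e2)),
            class = "arma_params")
}

#' @export
print.arma_params <- function(x, ...) {
  cat(sprintf("ARMA(1,1): phi = %.6f, theta_ma = %.6f, sigma_e = %.6f\n",
              x$phi, x$theta_ma, x$sigma_e))
  invisible(x)
}

#' Autocovariance function of an ARMA(1,1) process
#'
#' @param arma An `arma_params` list (`phi`, `theta_ma`, `sigma_e`).
#' @param max_lag Largest lag.
#' @return Named numeric vector of autocovariances at lags `0..max_lag`.
#' @export
arma_autocovariance <- function(arma, max_lag = 10) {
  phi <- arma$phi; th <- arma$theta_ma; s2 <- arma$sigma_e^2
  if (abs(phi) >= 1) stop("non-stationary: |phi| must be < 1", call. = FALSE)
  g <- numeric(max_lag + 1)
  g[1] <- s2 * (1 + 2 * phi * th + th^2) / (1 - phi^2)
  if (max_lag >= 1) {
    g[2] <- s2 * (1 + phi * th) * (phi + th) / (1 - phi^2)
    for (k in seq_len(max_lag - 1) + 1) g[k + 1] <- phi * g[k]
  }
  stats::setNames(g, paste0("lag", 0:max_lag))
}

#' Parameter-redundancy index of the state-space model
#'
#' `|phi + theta_ma|` of the mapped ARMA(1,1): zero means the AR and MA
#' roots cancel exactly, leaving an observationally white-noise model
#' (complete redundancy — the parameters cannot be separated from the
#' data). The index shrinks as the measurement-error to process-noise
#' ratio grows, quantifying why estimation degrades precisely in the regime
#' where a state-space model is most wanted.
#'
#' @inheritParams ssm_autocovariance
#' @return Non-negative scalar.
#' @export
redundancy_index <- function(params) {
  a <- ssm_to_arma(params)
  abs(a$phi + a$theta_ma)
}
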