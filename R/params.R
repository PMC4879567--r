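#' Parameters of the univariate linear Gaussian state-space model
#'
#' The model is an AR(1) latent state observed with additive Gaussian noise:
#' \deqn{x_t = \rho x_{t-1} + \eta_t, \quad \eta_t \sim N(0, \sigma_\eta^2)}
#' \deqn{y_t = x_t + \epsilon_t, \quad \epsilon_t \sim N(0, \sigma_\epsilon^2)}
#' The initial state is either known exactly (`x0_prior = "known"`, the value
#' in `x0`) or Gaussian, `x_0 ~ N(x0, sigma0^2)` (`x0_prior = "gaussian"`).
#'
#' @param sigma_eps Measurement-error standard deviation (state units), >= 0.
#' @param rho Autoregression coefficient of the latent state (dimensionless).
#' @param sigma_eta Process (innovation) standard deviation (state units), >= 0.
#' @param x0 Initial state value (known case) or prior mean (Gaussian case).
#' @param x0_prior `"known"` or `"gaussian"`.
#' @param sigma0 Prior standard deviation of the initial state; required > 0
#'   when `x0_prior = "gaussian"`.
#'
#' @return An object of class `ssm_params`.
#' @examples
#' ssm_params(sigma_eps = 0.1, rho = 0.7, sigma_eta = 0.2)
#' @export
ssm_params <- function(sigma_eps, rho, sigma_eta, x0 = 0,
                       x0_prior = c("known", "gaussian"), sigma0 = NULL) {
  x0_prior <- match.arg(x0_prior)
  stopifnot(is.numeric(sigma_eps), is.numeric(rho), is.numeric(sigma_eta),
            length(sigma_eps) == 1L, length(rho) == 1L, length(sigma_eta) == 1L)
  if (!is.finite(sigma_eps) || sigma_eps < 0)
    stop("invalid configuration: sigma_eps must be finite and >= 0", call. = FALSE)
  if (!is.finite(sigma_eta) || sigma_eta < 0)
    stop("invalid configuration: sigma_eta must be finite and >= 0", call. = FALSE)
  if (!is.finite(rho)) stop("invalid configuration: rho must be finite", call. = FALSE)
  if (x0_prior == "gaussian") {
    if (is.null(sigma0) || !is.finite(sigma0) || sigma0 <= 0)
      stop("invalid configuration: gaussian x0 prior needs sigma0 > 0", call. = FALSE)
  } else {
    sigma0 <- 0
  }
  structure(
    list(sigma_eps = sigma_eps, rho = rho, sigma_eta = sigma_eta,
         x0 = x0, x0_prior = x0_prior, sigma0 = sigma0),
    class = "ssm_params"
  )
}

#' @export
print.ssm_params <- function(x, ...) {
  cat("Linear Gaussian SSM parameters\n")
  cat(sprintf("  sigma_eps = %g, rho = %g, sigma_eta = %g\n",
              x$sigma_eps, x$rho, x$sigma_eta))
  if (x$x0_prior == "known") {
    cat(sprintf("  x0 = %g (known)\n", x$x0))
  } else {
    cat(sprintf("  x0 ~ N(%g, %g^2)\n", x$x0, x$sigma0))
  }
  invisible(x)
}

#' Bundle an observation series (and optional truth) for model fitting
#'
#' @param y Numeric vector of observations; `NA` marks a missing day.
#' @param x_true Optional vector of true latent states (simulated data only);
#'   must be complete and the same length as `y`.
#' @param seed Optional integer recording the generator seed that produced
#'   the series.
#'
#' @return An object of class `ssm_series` with elements `y`, `x_true`,
#'   `n`, `seed`.
#' @export
ssm_series <- function(y, x_true = NULL, seed = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("invalid configuration: series must have n >= 1", call. = FALSE)
  if (!is.null(x_true)) {
    x_true <- as.numeric(x_true)
    if (length(x_true) != n)
      stop("x_true must have the same length as y", call. = FALSE)
    if (anyNA(x_true))
      stop("x_true must not contain missing values", call. = FALSE)
  }
  structure(list(y = y, x_true = x_true, n = n, seed = seed),
            class = "ssm_series")
}

#' @export
print.ssm_series <- function(x, ...) {
  cat(sprintf("ssm_series: n = %d, %d missing, truth %s\n",
              x$n, sum(is.na(x$y)),
              if (is.null(x$x_true)) "absent" else "present"))
  invisible(x)
}

as_ssm_series <- function(series) {
  if (inherits(series, "ssm_series")) return(series)
  if (is.numeric(series)) return(ssm_series(series))
  stop("expected an ssm_series or a numeric vector", call. = FALSE)
}
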