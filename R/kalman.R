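#' Kalman filter marginal log-likelihood
#'
#' Evaluates the exact marginal log-likelihood of the observed entries of
#' `y` under the linear Gaussian state-space model, by the prediction-error
#' decomposition, and returns the filtering recursions. Missing observations
#' skip the update step and propagate the prediction, so the likelihood is
#' that of the observed entries only.
#'
#' @param params An [ssm_params()] object.
#' @param series An [ssm_series()] or numeric vector (`NA` = missing).
#' @return A list of class `kalman_output` with per-time-step
#'   `pred_mean`/`pred_var`, `filt_mean`/`filt_var`, the total `loglik`
#'   (nats), `n_obs`, and `n_clipped` (variance-floor activations). An
#'   all-missing series has `loglik = 0`.
#' @seealso [kalman_smooth()] for smoothed state estimates.
#' @export
kalman_filter_loglik <- function(params, series) {
  .kalman_pass(params, series, smooth = FALSE)
}

#' Kalman (RTS) smoother
#'
#' Runs the filter and the Rauch-Tung-Striebel backward recursion, returning
#' smoothed state means and variances `E[x_t | y_1..y_n]`,
#' `Var[x_t | y_1..y_n]` in `sm_mean`/`sm_var`, alongside everything
#' [kalman_filter_loglik()] returns.
#'
#' @inheritParams kalman_filter_loglik
#' @export
kalman_smooth <- function(params, series) {
  .kalman_pass(params, series, smooth = TRUE)
}

.kalman_pass <- function(params, series, smooth) {
  stopifnot(inherits(params, "ssm_params"))
  series <- as_ssm_series(series)
  p0 <- if (params$x0_prior == "gaussian") params$sigma0^2 else 0
  out <- kalman_pass_cpp(series$y, params$rho,
                         params$sigma_eta^2, params$sigma_eps^2,
                         params$x0, p0, smooth)
  if (isTRUE(out$degenerate))
    stop("degenerate likelihood: zero-variance model inconsistent with the observations",
         call. = FALSE)
  out$degenerate <- NULL
  class(out) <- "kalman_output"
  out
}

#' @export
print.kalman_output <- function(x, ...) {
  cat(sprintf("kalman_output: %d observed steps, loglik = %.6f\n",
              x$n_obs, x$loglik))
  invisible(x)
}

# Fast scalar likelihood used inside optimisation loops.
.loglik_fast <- function(y, sigma_eps, rho, sigma_eta, x0, p0) {
  kalman_loglik_cpp(y, rho, sigma_eta^2, sigma_eps^2, x0, p0)
}

#' Complete-data log-likelihood with known states
#'
#' The joint log-likelihood of a fully observed state path and the
#' observations: `sum_t log N(x_t; rho * x_{t-1}, sigma_eta^2) +
#' sum_t log N(y_t; x_t, sigma_eps^2)`, the observation sum running over
#' non-missing `y_t` only. Used by the known-states estimability diagnostic.
#' A zero standard deviation with a nonzero residual yields `-Inf` with
#' attribute `degenerate = TRUE`.
#'
#' @inheritParams kalman_filter_loglik
#' @param states Complete state path `x_1..x_n` (same length as `y`). The
#'   transition term at `t = 1` conditions on `params$x0` (plus the Gaussian
#'   prior variance when `x0_prior = "gaussian"`).
#' @return A single log-likelihood value (nats).
#' @export
joint_loglik_known_states <- function(params, states, series) {
  stopifnot(inherits(params, "ssm_params"))
  series <- as_ssm_series(series)
  states <- as.numeric(states)
  if (length(states) != series$n)
    stop("states must have the same length as the observations", call. = FALSE)
  if (anyNA(states)) stop("states must be complete", call. = FALSE)

  prev <- c(params$x0, states[-length(states)])
  trans_var <- rep(params$sigma_eta^2, series$n)
  # a Gaussian x0 prior folds into the first transition variance
  if (params$x0_prior == "gaussian")
    trans_var[1] <- trans_var[1] + params$rho^2 * params$sigma0^2
  trans_resid <- states - params$rho * prev
  obs <- !is.na(series$y)
  obs_resid <- series$y[obs] - states[obs]

  ll_part <- function(resid, var) {
    zero <- var == 0
    # point mass: met exactly contributes 0, violated kills the likelihood
    if (any(abs(resid[zero]) > 0)) return(-Inf)
    sum(stats::dnorm(resid[!zero], 0, sqrt(var[!zero]), log = TRUE))
  }
  ll <- ll_part(trans_resid, trans_var) +
    ll_part(obs_resid, rep(params$sigma_eps^2, sum(obs)))
  if (!is.finite(ll)) {
    attr(ll, "degenerate") <- TRUE
  }
  ll
}
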