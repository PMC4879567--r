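#' Profile log-likelihood for one parameter
#'
#' For each grid value of the focal parameter, re-optimizes the remaining
#' free parameters (multi-start) and records the profiled log-likelihood.
#' The profile is scanned for flat segments (runs of grid points whose
#' log-likelihood range is below `flat_tol`) and for local maxima (peaks
#' with prominence above `peak_tol`); flat or multimodal profiles are the
#' fingerprint of an estimability problem.
#'
#' @inheritParams fit_mle
#' @param focal One of `"sigma_eps"`, `"rho"`, `"sigma_eta"`.
#' @param grid Numeric vector of focal-parameter values (SDs must be >= 0).
#' @param states Optional complete true state path; when supplied the
#'   profile is of the complete-data (known-states) likelihood instead of
#'   the marginal likelihood.
#' @param fixed Additional parameters held fixed at every grid point.
#' @param flat_tol Log-likelihood range defining a flat run (nats).
#' @param flat_frac Fraction of the grid a flat run must cover to raise the
#'   flat flag.
#' @param peak_tol Minimum prominence (nats) for a local maximum to count.
#' @param level Confidence level of the chi-square profile cutoff.
#'
#' @return An object of class `ssm_profile`: `focal`, `grid`,
#'   `profile_loglik`, `loglik_max` (unconstrained optimum), `mle` (focal
#'   value at the optimum), `flat_segments` (list of index ranges),
#'   `is_flat`, `n_local_maxima`, `profile_ci` (grid values within the
#'   cutoff), and `valid` (per-point optimizer success).
#' @export
profile_likelihood <- function(series, focal, grid, states = NULL,
                               fixed = NULL, starts = NULL,
                               x0 = 0, x0_prior = c("known", "gaussian"),
                               sigma0 = NULL,
                               flat_tol = 0.05, flat_frac = 0.2,
                               peak_tol = 0.05, level = 0.95) {
  x0_prior <- match.arg(x0_prior)
  focal <- match.arg(focal, .PARAM_NAMES)
  series <- as_ssm_series(series)
  if (focal %in% .SD_PARAMS && any(grid < 0))
    stop("grid values for an SD parameter must be >= 0", call. = FALSE)
  if (!is.null(fixed) && focal %in% names(fixed))
    stop("focal parameter cannot also be in fixed", call. = FALSE)

  fit_at <- function(extra_fixed) {
    if (is.null(states)) {
      fit_mle(series, fixed = c(fixed, extra_fixed), starts = starts,
              x0 = x0, x0_prior = x0_prior, sigma0 = sigma0)
    } else {
      fit_known_states(series, states, fixed = c(fixed, extra_fixed),
                       starts = starts, x0 = x0)
    }
  }

  full_fit <- fit_at(NULL)
  prof <- rep(NA_real_, length(grid))
  valid <- rep(FALSE, length(grid))
  for (i in seq_along(grid)) {
    gi <- stats::setNames(grid[i], focal)
    res <- tryCatch(fit_at(gi), error = function(e) NULL)
    if (!is.null(res) && is.finite(res$loglik_max)) {
      prof[i] <- res$loglik_max
      valid[i] <- TRUE
    }
  }

  flat <- .flat_segments(prof, flat_tol)
  flat_len <- if (length(flat)) max(vapply(flat, function(s) s[2] - s[1] + 1L,
                                           integer(1))) else 0L
  cutoff <- max(prof, na.rm = TRUE) - stats::qchisq(level, df = 1) / 2

  structure(list(
    focal = focal, grid = grid, profile_loglik = prof, valid = valid,
    loglik_max = full_fit$loglik_max, mle = full_fit$theta_hat[[focal]],
    flat_segments = flat,
    is_flat = flat_len >= flat_frac * length(grid),
    n_local_maxima = .count_local_maxima(prof, peak_tol),
    profile_ci = grid[!is.na(prof) & prof >= cutoff],
    flat_tol = flat_tol, peak_tol = peak_tol
  ), class = "ssm_profile")
}

#' @export
print.ssm_profile <- function(x, ...) {
  cat(sprintf("profile of %s over %d points: %d local maxima, flat = %s\n",
              x$focal, length(x$grid), x$n_local_maxima, x$is_flat))
  invisible(x)
}

# maximal runs of consecutive valid points with loglik range < tol,
# returned as list of c(start, end) index pairs (runs of length >= 2)
.flat_segments <- function(prof, tol) {
  n <- length(prof)
  segs <- list()
  i <- 1L
  while (i < n) {
    if (is.na(prof[i])) { i <- i + 1L; next }
    j <- i
    lo <- prof[i]; hi <- prof[i]
    while (j < n && !is.na(prof[j + 1L]) &&
           max(hi, prof[j + 1L]) - min(lo, prof[j + 1L]) < tol) {
      j <- j + 1L
      lo <- min(lo, prof[j]); hi <- max(hi, prof[j])
    }
    if (j > i) segs[[length(segs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  segs
}

# peak count with a prominence rule: a local maximum counts when it rises
# at least `tol` above the deepest valley separating it from a higher peak
.count_local_maxima <- function(prof, tol) {
  v <- prof[!is.na(prof)]
  if (length(v) < 3L) return(as.integer(length(v) > 0))
  # candidate peaks: strictly-higher-than-neighbour points (plateau-safe)
  n <- length(v)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) v[i - 1L] else -Inf
    right <- if (i < n) v[i + 1L] else -Inf
    is_peak[i] <- v[i] >= left && v[i] >= right && (v[i] > left || v[i] > right)
  }
  peaks <- which(is_peak)
  if (length(peaks) <= 1L) return(max(1L, length(peaks)))
  keep <- 0L
  for (p in peaks) {
    higher <- peaks[v[peaks] > v[p]]
    if (length(higher) == 0L) { keep <- keep + 1L; next }
    # prominence relative to the nearest higher peak
    proms <- vapply(higher, function(h) {
      rng <- if (h < p) v[h:p] else v[p:h]
      v[p] - min(rng)
    }, numeric(1))
    if (min(proms) >= tol) keep <- keep + 1L
  }
  max(1L, keep)
}

#' Two-parameter profile log-likelihood surface
#'
#' For every cell of `grid_a` x `grid_b`, fixes the two focal parameters and
#' re-optimizes the remaining free parameter(s). A ridge of near-constant
#' log-likelihood along a trade-off curve between a process and a
#' measurement variance is the classic signature of parameter redundancy.
#'
#' @inheritParams profile_likelihood
#' @param param_a,param_b Names of the two focal parameters.
#' @param grid_a,grid_b Grids for each.
#' @return An object of class `ssm_surface`: the `loglik` matrix
#'   (rows = `grid_a`, cols = `grid_b`), the grids and parameter names, and
#'   `loglik_max` of the unconstrained fit.
#' @export
likelihood_surface <- function(series, param_a, param_b, grid_a, grid_b,
                               fixed = NULL, starts = NULL,
                               x0 = 0, x0_prior = c("known", "gaussian"),
                               sigma0 = NULL) {
  x0_prior <- match.arg(x0_prior)
  param_a <- match.arg(param_a, .PARAM_NAMES)
  param_b <- match.arg(param_b, .PARAM_NAMES)
  if (param_a == param_b) stop("param_a and param_b must differ", call. = FALSE)
  series <- as_ssm_series(series)

  full_fit <- fit_mle(series, fixed = fixed, starts = starts,
                      x0 = x0, x0_prior = x0_prior, sigma0 = sigma0)
  m <- matrix(NA_real_, length(grid_a), length(grid_b))
  for (i in seq_along(grid_a)) {
    for (j in seq_along(grid_b)) {
      fx <- c(fixed, stats::setNames(c(grid_a[i], grid_b[j]),
                                     c(param_a, param_b)))
      res <- tryCatch(
        fit_mle(series, fixed = fx, starts = starts, x0 = x0,
                x0_prior = x0_prior, sigma0 = sigma0),
        error = function(e) NULL)
      if (!is.null(res)) m[i, j] <- res$loglik_max
    }
  }
  structure(list(param_a = param_a, param_b = param_b,
                 grid_a = grid_a, grid_b = grid_b,
                 loglik = m, loglik_max = full_fit$loglik_max),
            class = "ssm_surface")
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `B` series from the fitted parameters, refits each (same fixed
#' parameters and multi-start policy), and returns percentile confidence
#' intervals for the parameters. State intervals are obtained by
#' re-smoothing the original series under each bootstrap parameter
#' estimate, giving a percentile band that propagates parameter uncertainty
#' into the state estimates. Refits that fail are dropped and counted.
#'
#' @param fit An `ssm_fit` from [fit_mle()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; replicate `b` uses `seed + b`.
#' @param series_length Length of the simulated series (defaults to the
#'   length of the fitted series).
#' @param level Interval coverage (default 0.95).
#' @return An object of class `ssm_bootstrap`: matrix `theta` (B_ok x 3) of
#'   bootstrap estimates, `ci` (percentile intervals per parameter),
#'   `state_ci` (per-time-point percentile band for the smoothed states of
#'   the original series), and `n_failed`.
#' @export
parametric_bootstrap <- function(fit, B, seed, series_length = NULL,
                                 level = 0.95) {
  stopifnot(inherits(fit, "ssm_fit"), B >= 1)
  if (!isTRUE(fit$converged))
    warning("bootstrapping a fit that did not converge")
  if (is.null(series_length)) series_length <- fit$series$n
  th <- fit$theta_hat
  p <- ssm_params(th[["sigma_eps"]], th[["rho"]], th[["sigma_eta"]],
                  x0 = fit$x0, x0_prior = fit$x0_prior,
                  sigma0 = fit$sigma0)
  fixed <- NULL
  if (any(fit$fixed_mask))
    fixed <- th[fit$fixed_mask]

  thetas <- matrix(NA_real_, B, 3L, dimnames = list(NULL, .PARAM_NAMES))
  states <- matrix(NA_real_, B, fit$series$n)
  n_failed <- 0L
  for (b in seq_len(B)) {
    sim <- simulate_ssm(p, n = series_length, seed = seed + b)
    rb <- tryCatch(
      fit_mle(sim, fixed = fixed, x0 = fit$x0, x0_prior = fit$x0_prior,
              sigma0 = fit$sigma0),
      error = function(e) NULL)
    if (is.null(rb)) { n_failed <- n_failed + 1L; next }
    thetas[b, ] <- rb$theta_hat
    pb <- ssm_params(rb$theta_hat[["sigma_eps"]], rb$theta_hat[["rho"]],
                     rb$theta_hat[["sigma_eta"]], x0 = fit$x0,
                     x0_prior = fit$x0_prior, sigma0 = fit$sigma0)
    states[b, ] <- kalman_smooth(pb, fit$series)$sm_mean
  }
  ok <- stats::complete.cases(thetas)
  thetas <- thetas[ok, , drop = FALSE]
  states <- states[ok, , drop = FALSE]
  probs <- c((1 - level) / 2, (1 + level) / 2)
  ci <- t(apply(thetas, 2L, stats::quantile, probs = probs, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  state_ci <- t(apply(states, 2L, stats::quantile, probs = probs,
                      names = FALSE))
  colnames(state_ci) <- c("lower", "upper")
  structure(list(theta = thetas, ci = ci, state_ci = state_ci,
                 n_failed = n_failed, level = level, B = B),
            class = "ssm_bootstrap")
}

#' @export
print.ssm_bootstrap <- function(x, ...) {
  cat(sprintf("parametric bootstrap: %d replicates (%d failed)\n",
              x$B, x$n_failed))
  print(round(x$ci, 5))
  invisible(x)
}
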