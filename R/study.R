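#' Root mean square error between state sequences
#'
#' `sqrt(mean((estimated - truth)^2))`, the state-recovery error used to
#' compare smoothing under estimated versus true parameters.
#'
#' @param estimated,truth Equal-length numeric vectors; `truth` complete.
#' @return A single non-negative number.
#' @export
state_rmse <- function(estimated, truth) {
  estimated <- as.numeric(estimated)
  truth <- as.numeric(truth)
  if (length(estimated) != length(truth))
    stop("estimated and truth must have equal length", call. = FALSE)
  if (anyNA(truth)) stop("truth must be complete", call. = FALSE)
  sqrt(mean((estimated - truth)^2))
}

#' Scenario and study configurations for the simulation experiments
#'
#' A scenario fixes the generating parameters of one cell of the simulation
#' grid; a study configuration sweeps `sigma_eta` over a grid with a number
#' of replicates per scenario. Defaults reproduce the main experiment:
#' `rho = 0.7`, `sigma_eps = 0.1`, known `x0 = 0`, `n = 100`, 200
#' replicates at each `sigma_eta` in (0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1).
#'
#' @param sigma_eta_grid Process-SD values to sweep.
#' @param n_replicates Replicates per scenario.
#' @param n Series length.
#' @param rho,sigma_eps,x0 Generating values of the remaining parameters.
#' @param base_seed Base seed; replicate `i` of scenario `j` uses
#'   `base_seed + (j - 1) * n_replicates + i`, so results are independent
#'   of execution order.
#' @param fit_free,fit_fixed_eps Which fits to run per replicate: the free
#'   fit estimates all three parameters; the fixed fit holds `sigma_eps` at
#'   its generating value and estimates the rest.
#' @param interior_only Passed to [fit_mle()].
#' @return A `study_config` list.
#' @export
study_config <- function(sigma_eta_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                         n_replicates = 200, n = 100,
                         rho = 0.7, sigma_eps = 0.1, x0 = 0,
                         base_seed = 1L,
                         fit_free = TRUE, fit_fixed_eps = FALSE,
                         interior_only = FALSE) {
  stopifnot(length(sigma_eta_grid) >= 1, all(sigma_eta_grid >= 0),
            n_replicates >= 1, n >= 3, sigma_eps >= 0)
  structure(list(sigma_eta_grid = sigma_eta_grid,
                 n_replicates = as.integer(n_replicates), n = as.integer(n),
                 rho = rho, sigma_eps = sigma_eps, x0 = x0,
                 base_seed = as.integer(base_seed),
                 fit_free = fit_free, fit_fixed_eps = fit_fixed_eps,
                 interior_only = interior_only),
            class = "study_config")
}

#' Run one simulation replicate
#'
#' Simulates a series at the scenario's generating parameters, fits the
#' model (free and/or `sigma_eps`-fixed), then smooths the series once under
#' the estimated and once under the true parameters and records both state
#' RMSEs. Non-converged fits are retained with their flags rather than
#' raising an error, so a study never aborts mid-grid.
#'
#' @param sigma_eta Process SD of the scenario.
#' @param seed Replicate seed.
#' @param config A [study_config()] (supplies `n`, `rho`, `sigma_eps`,
#'   `x0`, fit modes).
#' @return One-row data frame with the scenario, seed, parameter estimates,
#'   flags, and `rmse_true`, `rmse_hat` (free fit) and `rmse_hat_fixed`
#'   (fixed fit, `NA` when not run).
#' @export
run_replicate <- function(sigma_eta, seed, config = study_config()) {
  truth <- ssm_params(config$sigma_eps, config$rho, sigma_eta, x0 = config$x0)
  sim <- simulate_ssm(truth, n = config$n, seed = seed)

  sm_true <- kalman_smooth(truth, sim)
  rmse_true <- state_rmse(sm_true$sm_mean, sim$x_true)

  row <- data.frame(sigma_eta = sigma_eta, n = config$n, rho = config$rho,
                    sigma_eps = config$sigma_eps, seed = seed,
                    rmse_true = rmse_true,
                    rmse_hat = NA_real_, rmse_hat_fixed = NA_real_,
                    est_sigma_eps = NA_real_, est_rho = NA_real_,
                    est_sigma_eta = NA_real_,
                    est_rho_fixed = NA_real_, est_sigma_eta_fixed = NA_real_,
                    converged = NA, converged_fixed = NA,
                    boundary_sigma_eps = NA, boundary_sigma_eta = NA,
                    boundary_sigma_eta_fixed = NA,
                    loglik_free = NA_real_, loglik_fixed = NA_real_)

  # true-parameters-only mode: the only smoother run is the one under the
  # generating parameters, so the "estimated" RMSE coincides with rmse_true
  if (!config$fit_free && !config$fit_fixed_eps)
    row$rmse_hat <- rmse_true

  smooth_rmse <- function(theta) {
    p <- ssm_params(theta[["sigma_eps"]], theta[["rho"]], theta[["sigma_eta"]],
                    x0 = config$x0)
    state_rmse(kalman_smooth(p, sim)$sm_mean, sim$x_true)
  }

  if (config$fit_free) {
    fit <- tryCatch(
      fit_mle(sim, x0 = config$x0, interior_only = config$interior_only),
      error = function(e) NULL)
    if (!is.null(fit)) {
      row$rmse_hat <- smooth_rmse(fit$theta_hat)
      row$est_sigma_eps <- fit$theta_hat[["sigma_eps"]]
      row$est_rho <- fit$theta_hat[["rho"]]
      row$est_sigma_eta <- fit$theta_hat[["sigma_eta"]]
      row$converged <- fit$converged
      row$boundary_sigma_eps <- fit$boundary_flags[["sigma_eps"]]
      row$boundary_sigma_eta <- fit$boundary_flags[["sigma_eta"]]
      row$loglik_free <- fit$loglik_max
    } else {
      row$converged <- FALSE
    }
  }
  if (config$fit_fixed_eps) {
    fitf <- tryCatch(
      fit_mle(sim, fixed = c(sigma_eps = config$sigma_eps), x0 = config$x0,
              interior_only = config$interior_only),
      error = function(e) NULL)
    if (!is.null(fitf)) {
      row$rmse_hat_fixed <- smooth_rmse(fitf$theta_hat)
      row$est_rho_fixed <- fitf$theta_hat[["rho"]]
      row$est_sigma_eta_fixed <- fitf$theta_hat[["sigma_eta"]]
      row$converged_fixed <- fitf$converged
      row$boundary_sigma_eta_fixed <- fitf$boundary_flags[["sigma_eta"]]
      row$loglik_fixed <- fitf$loglik_max
    } else {
      row$converged_fixed <- FALSE
    }
  }
  row
}

#' Run the full simulation study
#'
#' Sweeps the `sigma_eta` grid, running `n_replicates` independent
#' replicates per scenario with seeds bound to the replicate index (results
#' are deterministic given `base_seed` and independent of execution order).
#'
#' @param config A [study_config()].
#' @return An object of class `ssm_study`: the `config`, a data frame
#'   `replicates` (one row per replicate, see [run_replicate()]), and
#'   `n_failed` per fit mode.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  rows <- vector("list", length(config$sigma_eta_grid) * config$n_replicates)
  k <- 0L
  for (j in seq_along(config$sigma_eta_grid)) {
    for (i in seq_len(config$n_replicates)) {
      k <- k + 1L
      seed <- config$base_seed + (j - 1L) * config$n_replicates + i
      rows[[k]] <- run_replicate(config$sigma_eta_grid[j], seed, config)
    }
  }
  reps <- do.call(rbind, rows)
  structure(list(config = config, replicates = reps,
                 n_failed = c(free = sum(config$fit_free & is.na(reps$rmse_hat)),
                              fixed = sum(config$fit_fixed_eps &
                                            is.na(reps$rmse_hat_fixed)))),
            class = "ssm_study")
}

#' @export
print.ssm_study <- function(x, ...) {
  cat(sprintf("ssm_study: %d scenarios x %d replicates (n = %d)\n",
              length(x$config$sigma_eta_grid), x$config$n_replicates,
              x$config$n))
  invisible(x)
}

#' Percentage of replicates whose state error inflates under estimation
#'
#' `100 x` the fraction of replicates whose smoothed-state RMSE under the
#' estimated parameters is at least `factor` times the RMSE under the true
#' parameters. This is the study's headline measure of how often parameter
#' estimation corrupts state recovery.
#'
#' @param study An `ssm_study` from [run_study()], or its `replicates`
#'   data frame.
#' @param factor Ratio threshold (default 1.5, i.e. "50% larger").
#' @param which_fit `"free"` (all parameters estimated) or `"fixed_eps"`
#'   (`sigma_eps` held at its generating value).
#' @param by_scenario If `TRUE`, returns a per-`sigma_eta` breakdown instead
#'   of the pooled percentage.
#' @return Pooled percentage, or a data frame with columns `sigma_eta`,
#'   `percent` when `by_scenario = TRUE`.
#' @export
proportion_exceeding <- function(study, factor = 1.5,
                                 which_fit = c("free", "fixed_eps"),
                                 by_scenario = FALSE) {
  which_fit <- match.arg(which_fit)
  reps <- if (inherits(study, "ssm_study")) study$replicates else study
  if (is.null(reps) || nrow(reps) == 0L)
    stop("empty study", call. = FALSE)
  hat <- if (which_fit == "free") reps$rmse_hat else reps$rmse_hat_fixed
  if (all(is.na(hat)))
    stop("requested fit mode was not run in this study", call. = FALSE)
  exceeds <- hat >= factor * reps$rmse_true
  if (!by_scenario) return(100 * mean(exceeds, na.rm = TRUE))
  agg <- stats::aggregate(exceeds, by = list(sigma_eta = reps$sigma_eta),
                          FUN = function(z) 100 * mean(z, na.rm = TRUE))
  names(agg)[2] <- "percent"
  agg
}

#' Flag a bimodal empirical distribution
#'
#' A kernel-density two-mode check: the density of `x` is scanned for local
#' maxima, and modes below `prominence` (as a fraction of the density
#' range) are discarded. Returns the retained mode locations; the
#' distribution is flagged bimodal when two or more survive. Degenerate
#' samples (zero spread) are never flagged.
#'
#' @param x Numeric sample.
#' @param prominence Minimum peak prominence as a fraction of the density
#'   range (default 0.05).
#' @return List with `bimodal` (logical) and `modes` (locations).
#' @export
bimodality_check <- function(x, prominence = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5L || stats::sd(x) == 0)
    return(list(bimodal = FALSE, modes = if (length(x)) mean(x) else numeric(0)))
  d <- stats::density(x, n = 512)
  y <- d$y
  n <- length(y)
  peaks <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (length(peaks) > 1L) {
    tol <- prominence * diff(range(y))
    keep <- logical(length(peaks))
    for (k in seq_along(peaks)) {
      p <- peaks[k]
      higher <- peaks[y[peaks] > y[p]]
      if (length(higher) == 0L) { keep[k] <- TRUE; next }
      proms <- vapply(higher, function(h) {
        rng <- if (h < p) y[h:p] else y[p:h]
        y[p] - min(rng)
      }, numeric(1))
      keep[k] <- min(proms) >= tol
    }
    peaks <- peaks[keep]
  }
  list(bimodal = length(peaks) >= 2L, modes = d$x[peaks])
}

#' Per-scenario summaries of a simulation study
#'
#' For each `sigma_eta` scenario: quantiles of the parameter estimates and
#' both state RMSEs, the proportion of boundary estimates per variance
#' component, and bimodality flags for each estimate's distribution (with
#' an indicator for a mode near zero, the signature seen in the estimate
#' distributions of `sigma_eps` and `rho` when measurement error dominates).
#'
#' @param study An `ssm_study`.
#' @param which_fit `"free"` or `"fixed_eps"`.
#' @param near_zero_frac A mode counts as "near zero" when its location is
#'   within this fraction of the estimate range above the minimum scale
#'   (default 0.1).
#' @return Data frame, one row per scenario.
#' @export
summarize_study <- function(study, which_fit = c("free", "fixed_eps"),
                            near_zero_frac = 0.1) {
  which_fit <- match.arg(which_fit)
  stopifnot(inherits(study, "ssm_study"))
  reps <- study$replicates
  if (nrow(reps) == 0L) stop("empty study", call. = FALSE)
  cols <- if (which_fit == "free") {
    list(sigma_eps = "est_sigma_eps", rho = "est_rho",
         sigma_eta = "est_sigma_eta", rmse_hat = "rmse_hat",
         boundary_eps = "boundary_sigma_eps",
         boundary_eta = "boundary_sigma_eta")
  } else {
    list(sigma_eps = NULL, rho = "est_rho_fixed",
         sigma_eta = "est_sigma_eta_fixed", rmse_hat = "rmse_hat_fixed",
         boundary_eps = NULL, boundary_eta = "boundary_sigma_eta_fixed")
  }
  near_zero <- function(modes, values) {
    if (!length(modes)) return(FALSE)
    scale <- max(abs(values), na.rm = TRUE)
    if (scale == 0) return(FALSE)
    any(abs(modes) <= near_zero_frac * scale)
  }
  out <- lapply(split(reps, reps$sigma_eta), function(g) {
    row <- data.frame(sigma_eta = g$sigma_eta[1], n_replicates = nrow(g))
    for (pn in c("sigma_eps", "rho", "sigma_eta")) {
      cn <- cols[[pn]]
      if (is.null(cn)) next
      v <- g[[cn]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      bc <- bimodality_check(v)
      row[[paste0(pn, "_median")]] <- q[2]
      row[[paste0(pn, "_q25")]] <- q[1]
      row[[paste0(pn, "_q75")]] <- q[3]
      row[[paste0(pn, "_bimodal")]] <- bc$bimodal
      row[[paste0(pn, "_near_zero_mode")]] <- near_zero(bc$modes, v)
    }
    for (bn in c("boundary_eps", "boundary_eta")) {
      cn <- cols[[bn]]
      if (is.null(cn)) next
      row[[paste0("prop_", bn)]] <- mean(g[[cn]], na.rm = TRUE)
    }
    rq <- stats::quantile(g[[cols$rmse_hat]], c(0.25, 0.5, 0.75),
                          na.rm = TRUE, names = FALSE)
    tq <- stats::quantile(g$rmse_true, c(0.25, 0.5, 0.75),
                          na.rm = TRUE, names = FALSE)
    row$rmse_hat_median <- rq[2]; row$rmse_hat_q25 <- rq[1]
    row$rmse_hat_q75 <- rq[3]
    row$rmse_true_median <- tq[2]; row$rmse_true_q25 <- tq[1]
    row$rmse_true_q75 <- tq[3]
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sigma_eta), , drop = FALSE]
}
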