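#' Simulate a univariate linear Gaussian state-space series
#'
#' Draws a latent AR(1) path `x_t = rho * x_{t-1} + eta_t` and observations
#' `y_t = x_t + eps_t`. When the initial-state prior is Gaussian the path
#' starts from a draw of `x_0 ~ N(x0, sigma0^2)`; with a known initial state
#' the recursion starts exactly at `x0` (no burn-in). Bit-reproducible for a
#' given seed.
#'
#' @param params An [ssm_params()] object.
#' @param n Series length (number of observations), >= 1.
#' @param seed Integer seed for the random generator.
#' @param missing_rate Fraction of observations independently marked missing
#'   (`NA` in `y`); the true states are always complete.
#' @return An [ssm_series()] with `x_true` attached.
#' @examples
#' s <- simulate_ssm(ssm_params(0.1, 0.7, 0.2), n = 100, seed = 1)
#' @export
simulate_ssm <- function(params, n, seed, missing_rate = 0) {
  stopifnot(inherits(params, "ssm_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("invalid configuration: n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid configuration: missing_rate must be in [0, 1)", call. = FALSE)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))

  x0 <- if (params$x0_prior == "gaussian")
    stats::rnorm(1L, params$x0, params$sigma0) else params$x0
  eta <- stats::rnorm(n, 0, params$sigma_eta)
  x <- numeric(n)
  prev <- x0
  for (t in seq_len(n)) {
    x[t] <- params$rho * prev + eta[t]
    prev <- x[t]
  }
  y <- x + stats::rnorm(n, 0, params$sigma_eps)
  if (missing_rate > 0) {
    y[stats::runif(n) < missing_rate] <- NA_real_
  }
  ssm_series(y, x_true = x, seed = as.integer(seed))
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Configuration for the synthetic bear-movement generator
#'
#' Describes a set of bear-like 2-D daily displacement series: a voluntary
#' AR(1) displacement per coordinate, an additive true ice drift, drift
#' observations corrupted by Gaussian error, and an i.i.d. missing-day
#' pattern. GPS error on the bear displacement itself is treated as zero
#' (negligible relative to daily movement scales).
#'
#' @param n_bears Number of bears.
#' @param n_days Days per bear (>= 2).
#' @param rho_u,rho_v Voluntary-displacement autocorrelation per coordinate.
#' @param sigma_q_u,sigma_q_v Voluntary-displacement process SDs (km/day).
#' @param sigma_h_u,sigma_h_v Ice-drift measurement-error SDs (km/day).
#' @param drift_sd SD of the true daily ice drift (km/day), i.i.d. per day.
#' @param init_sd Initial-state SD (km); default 15, the scale of observed
#'   daily bear displacements.
#' @param missing_rate Fraction of days with both bear and ice observations
#'   missing.
#' @param seed Base seed; bear `i` uses `seed + i`.
#' @return An object of class `bear_sim_config`.
#' @export
bear_sim_config <- function(n_bears = 15, n_days = 342,
                            rho_u = 0.7, rho_v = 0.7,
                            sigma_q_u = 10, sigma_q_v = 10,
                            sigma_h_u = 6, sigma_h_v = 6,
                            drift_sd = 5, init_sd = 15,
                            missing_rate = 0.05, seed = 1L) {
  sds <- c(sigma_q_u, sigma_q_v, sigma_h_u, sigma_h_v, drift_sd, init_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("invalid configuration: all SDs must be finite and >= 0", call. = FALSE)
  if (n_days < 2)
    stop("invalid configuration: n_days must be >= 2", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid configuration: missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(n_bears = as.integer(n_bears), n_days = as.integer(n_days),
                 rho_u = rho_u, rho_v = rho_v,
                 sigma_q_u = sigma_q_u, sigma_q_v = sigma_q_v,
                 sigma_h_u = sigma_h_u, sigma_h_v = sigma_h_v,
                 drift_sd = drift_sd, init_sd = init_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "bear_sim_config")
}

#' Simulate bear-like 2-D displacement series
#'
#' Per bear and coordinate, the voluntary displacement `c_t` follows an AR(1)
#' from `c_0 ~ N(0, init_sd^2)`; the true daily drift `g_t` is i.i.d.
#' `N(0, drift_sd^2)`; the observed bear displacement is `y_t = c_t + g_t`
#' (GPS error negligible) and the observed drift is `s_t = g_t + eps_t` with
#' `eps_t ~ N(0, sigma_h^2)`. A fraction `missing_rate` of days has both
#' `y_t` and `s_t` missing.
#'
#' @param config A [bear_sim_config()].
#' @return A data frame with columns `bear_id`, `t`, `y_u`, `y_v`, `s_u`,
#'   `s_v` (NA on missing days) and the simulated truth `c_u_true`,
#'   `c_v_true`, `g_u_true`, `g_v_true`.
#' @export
simulate_bear_paths <- function(config) {
  stopifnot(inherits(config, "bear_sim_config"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))

  one_coord <- function(n, rho, sigma_q, init_sd) {
    c0 <- stats::rnorm(1L, 0, init_sd)
    eta <- stats::rnorm(n, 0, sigma_q)
    x <- numeric(n)
    prev <- c0
    for (t in seq_len(n)) {
      x[t] <- rho * prev + eta[t]
      prev <- x[t]
    }
    x
  }

  out <- vector("list", config$n_bears)
  for (i in seq_len(config$n_bears)) {
    set.seed(config$seed + i)
    n <- config$n_days
    cu <- one_coord(n, config$rho_u, config$sigma_q_u, config$init_sd)
    cv <- one_coord(n, config$rho_v, config$sigma_q_v, config$init_sd)
    gu <- stats::rnorm(n, 0, config$drift_sd)
    gv <- stats::rnorm(n, 0, config$drift_sd)
    su <- gu + stats::rnorm(n, 0, config$sigma_h_u)
    sv <- gv + stats::rnorm(n, 0, config$sigma_h_v)
    yu <- cu + gu
    yv <- cv + gv
    miss <- stats::runif(n) < config$missing_rate
    yu[miss] <- NA_real_; yv[miss] <- NA_real_
    su[miss] <- NA_real_; sv[miss] <- NA_real_
    out[[i]] <- data.frame(bear_id = i, t = seq_len(n),
                           y_u = yu, y_v = yv, s_u = su, s_v = sv,
                           c_u_true = cu, c_v_true = cv,
                           g_u_true = gu, g_v_true = gv)
  }
  do.call(rbind, out)
}

#' Read and write time-series CSV files
#'
#' `write_series_csv()` writes columns `t`, `y` and, when present, `x_true`;
#' missing observations are written as empty cells. `read_series_csv()`
#' reads them back into an [ssm_series()].
#'
#' @param series An [ssm_series()].
#' @param path File path.
#' @return `read_series_csv()` returns an [ssm_series()];
#'   `write_series_csv()` returns `path` invisibly.
#' @export
write_series_csv <- function(series, path) {
  series <- as_ssm_series(series)
  df <- data.frame(t = seq_len(series$n), y = series$y)
  if (!is.null(series$x_true)) df$x_true <- series$x_true
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "y") %in% names(df)))
  ssm_series(df$y, x_true = if ("x_true" %in% names(df)) df$x_true else NULL)
}

#' Read and write bear displacement CSV files
#'
#' Schema: `bear_id`, `t`, `y_u`, `y_v`, `s_u`, `s_v`, with empty cells for
#' missing days; simulated-truth columns are passed through when present.
#'
#' @param bears Data frame as produced by [simulate_bear_paths()].
#' @param path File path.
#' @export
write_bear_csv <- function(bears, path) {
  utils::write.csv(bears, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_bear_csv
#' @export
read_bear_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("bear_id", "t", "y_u", "y_v", "s_u", "s_v") %in% names(df)))
  df
}
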