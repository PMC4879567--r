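#' Read and write model/simulation configurations as JSON
#'
#' `write_config_json()` serialises an [ssm_params()] or
#' [bear_sim_config()] (class tag included); `read_config_json()` restores
#' the object through its constructor, so invariants are re-checked on read.
#'
#' @param config An `ssm_params` or `bear_sim_config` object.
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  kind <- if (inherits(config, "ssm_params")) "ssm_params"
  else if (inherits(config, "bear_sim_config")) "bear_sim_config"
  else stop("unsupported config class", call. = FALSE)
  payload <- c(list(kind = kind), unclass(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$kind
  x$kind <- NULL
  if (identical(kind, "ssm_params")) {
    ssm_params(sigma_eps = x$sigma_eps, rho = x$rho, sigma_eta = x$sigma_eta,
               x0 = x$x0, x0_prior = x$x0_prior,
               sigma0 = if (identical(x$x0_prior, "gaussian")) x$sigma0 else NULL)
  } else if (identical(kind, "bear_sim_config")) {
    do.call(bear_sim_config, x)
  } else {
    stop("unrecognised config kind: ", kind, call. = FALSE)
  }
}

#' Write a fit result as JSON
#'
#' Flattens an `ssm_fit` into a plain JSON object (estimates, standard
#' errors, intervals, flags, log-likelihood) for downstream tabulation.
#'
#' @param fit An `ssm_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ssm_fit"))
  payload <- list(
    theta_hat = as.list(fit$theta_hat),
    se = as.list(fit$se),
    ci_low = as.list(fit$ci_low),
    ci_high = as.list(fit$ci_high),
    loglik_max = fit$loglik_max,
    converged = fit$converged,
    boundary_flags = as.list(fit$boundary_flags),
    fixed_mask = as.list(fit$fixed_mask),
    best_start_index = fit$best_start_index)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
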