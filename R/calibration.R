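#' Fit the empirical null distribution from negative-control estimates
#'
#' Models each negative-control log hazard ratio as
#' `log_hr_i ~ Normal(mu, tau^2 + se_i^2)`: `mu` is the mean systematic
#' error on the log scale and `tau` its spread, both assumed independent of
#' true effect size (the simplest model consistent with
#' negative-control calibration). Fitted by maximum likelihood with `tau`
#' parameterized as `log(tau)` plus an exact check of the `tau = 0`
#' boundary. Estimates flagged as excluded (e.g. zero-event controls) must
#' be dropped before calling.
#'
#' @param log_hr,se Negative-control point estimates and standard errors on
#'   the log-HR scale.
#' @param min_controls Minimum usable controls (default 5); below the floor
#'   calibration is skipped with a warning and `NULL` is returned so the
#'   caller can flag results as uncalibrated.
#' @return Object of class `empirical_null` with `mu`, `tau`, `n_controls`,
#'   `fit_loglik`, or `NULL` below the floor.
#' @export
fit_empirical_null <- function(log_hr, se, min_controls = 5) {
  keep <- is.finite(log_hr) & is.finite(se) & se > 0
  log_hr <- log_hr[keep]
  se <- se[keep]
  n <- length(log_hr)
  if (n < min_controls) {
    warn(sprintf(
      "only %d usable negative-control estimates (< %d); calibration skipped.",
      n, min_controls))
    return(NULL)
  }
  negll <- function(mu, tau) {
    -sum(stats::dnorm(log_hr, mu, sqrt(tau^2 + se^2), log = TRUE))
  }
  # tau = 0 boundary: mu is the precision-weighted mean
  w <- 1 / se^2
  mu0 <- sum(w * log_hr) / sum(w)
  ll0 <- -negll(mu0, 0)

  start_tau <- max(sqrt(max(0, var(log_hr) - mean(se^2))), 1e-3)
  opt <- optim(
    c(mu = mean(log_hr), log_tau = log(start_tau)),
    function(p) negll(p[1], exp(p[2])),
    method = "L-BFGS-B",
    lower = c(-10, log(1e-6)), upper = c(10, log(10))
  )
  if (-opt$value >= ll0) {
    mu <- unname(opt$par[1]); tau <- unname(exp(opt$par[2]))
    ll <- -opt$value
    if (tau < 1e-5) tau <- 0
  } else {
    mu <- mu0; tau <- 0; ll <- ll0
  }
  structure(
    list(mu = mu, tau = tau, n_controls = n, fit_loglik = ll),
    class = "empirical_null"
  )
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("<empirical_null>  mu = %.4f  tau = %.4f  (%d controls)\n",
              x$mu, x$tau, x$n_controls))
  invisible(x)
}

#' @rdname fit_empirical_null
#' @param x An `empirical_null`.
#' @param ... Unused.
#' @method tidy empirical_null
#' @export
tidy.empirical_null <- function(x, ...) {
  tibble::tibble(term = c("mu", "tau"), estimate = c(x$mu, x$tau))
}

#' @rdname fit_empirical_null
#' @method glance empirical_null
#' @export
glance.empirical_null <- function(x, ...) {
  tibble::tibble(mu = x$mu, tau = x$tau, n_controls = x$n_controls,
                 fit_loglik = x$fit_loglik)
}

#' Calibrated two-sided p-value
#'
#' The probability, under the fitted systematic-error model
#' `Normal(mu, tau^2 + se^2)`, of a log hazard ratio at least as extreme
#' as the one observed. Reduces to the standard Wald p-value when
#' `mu = 0, tau = 0`.
#'
#' @param log_hr,se Observed estimate(s) on the log scale.
#' @param null An [fit_empirical_null()] result.
#' @return Two-sided calibrated p-value(s).
#' @export
calibrate_p <- function(log_hr, se, null) {
  stopifnot(inherits(null, "empirical_null"))
  z <- (log_hr - null$mu) / sqrt(null$tau^2 + se^2)
  2 * pnorm(-abs(z))
}

#' Calibrated hazard ratio and confidence interval
#'
#' The calibrated interval is the set of effect sizes theta for which the
#' observed estimate lies within the central 95% of
#' `Normal(theta + mu, tau^2 + se^2)`: point estimate `log_hr - mu`,
#' half-width `1.959964 * sqrt(tau^2 + se^2)`. With `mu = 0, tau = 0` the
#' calibrated quantities equal the uncalibrated ones.
#'
#' @inheritParams calibrate_p
#' @return Tibble with `calibrated_log_hr`, `calibrated_se`,
#'   `calibrated_hr`, `calibrated_ci95_low`, `calibrated_ci95_high`,
#'   `calibrated_p`.
#' @export
calibrate_estimate <- function(log_hr, se, null) {
  stopifnot(inherits(null, "empirical_null"))
  cse <- sqrt(null$tau^2 + se^2)
  clhr <- log_hr - null$mu
  tibble::tibble(
    calibrated_log_hr = clhr,
    calibrated_se = cse,
    calibrated_hr = exp(clhr),
    calibrated_ci95_low = exp(clhr - Z95 * cse),
    calibrated_ci95_high = exp(clhr + Z95 * cse),
    calibrated_p = calibrate_p(log_hr, se, null)
  )
}

#' Append calibrated columns to an estimation-result table
#'
#' @param results Tibble of estimation results (needs `log_hr`,
#'   `se_log_hr`, `excluded`).
#' @param null An `empirical_null`, or `NULL` (results flagged
#'   uncalibrated).
#' @return `results` with the [calibrate_estimate()] columns and a
#'   `calibrated` flag; excluded rows keep `NA`s.
#' @export
calibrate_results <- function(results, null) {
  if (is.null(null)) {
    results$calibrated <- FALSE
    return(results)
  }
  cal <- calibrate_estimate(results$log_hr, results$se_log_hr, null)
  out <- dplyr::bind_cols(results, cal)
  out$calibrated <- !results$excluded
  out[results$excluded, names(cal)] <- NA_real_
  out
}
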