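#' Balance scatter plot (before vs after stratification)
#'
#' @param object A [balance_report()].
#' @param ... Unused.
#' @return A ggplot: |SMD| before stratification on x, after on y, with
#'   the balance threshold marked.
#' @method autoplot balance_report
#' @export
autoplot.balance_report <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = abs(.data$smd_before),
                               y = abs(.data$smd_after))) +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey60") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "|SMD| before stratification",
      y = "|SMD| after stratification",
      title = "Covariate balance",
      subtitle = sprintf("max |SMD| after = %.3f (threshold %.2f)",
                         attr(object, "max_abs_smd_after"), thr)
    ) +
    ggplot2::theme_minimal()
}

#' Propensity-score overlap plot
#'
#' @param scores Propensity scores (or a `ps_model`).
#' @param arm Arm labels (ignored when `scores` is a `ps_model` fitted
#'   with stored arms is not available; pass explicitly).
#' @return A ggplot of the score densities by arm.
#' @export
plot_ps_overlap <- function(scores, arm) {
  if (inherits(scores, "ps_model")) scores <- scores$scores
  d <- tibble::tibble(score = scores, arm = arm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$arm)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::labs(x = "Propensity score", y = "Density",
                  title = "Propensity-score overlap") +
    ggplot2::theme_minimal()
}

#' Forest plot of a meta-analysis
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot forest plot: one row per database and a pooled row
#'   only when the heterogeneity gate has not fired.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  d <- forest_data(object)
  d$label <- factor(d$label, levels = rev(d$label))
  sub <- if (object$gated) {
    sprintf("I² = %.2f ≥ gate: no pooled estimate",
            object$i_squared)
  } else {
    sprintf("pooled HR %.2f [%.2f, %.2f], I² = %.2f",
            object$pooled_hr, object$ci95_low, object$ci95_high,
            object$i_squared)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$label,
                                  colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci95_low, xmax = .data$ci95_high),
      height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL,
                  title = "Per-database and pooled estimates",
                  subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Negative-control calibration plot
#'
#' Shows each negative-control estimate against its standard error with
#' the region where the uncalibrated two-sided p-value is below 0.05 and
#' the fitted systematic-error band, the usual diagnostic for residual
#' confounding.
#'
#' @param object An `empirical_null`.
#' @param log_hr,se The negative-control estimates it was fitted on.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot empirical_null
#' @export
autoplot.empirical_null <- function(object, log_hr, se, ...) {
  d <- tibble::tibble(log_hr = log_hr, se = se)
  smax <- max(se) * 1.1
  band <- tibble::tibble(
    se = seq(1e-4, smax, length.out = 100)
  )
  band$lo <- object$mu - Z95 * sqrt(object$tau^2 + band$se^2)
  band$hi <- object$mu + Z95 * sqrt(object$tau^2 + band$se^2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$se, y = .data$log_hr)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$se, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_abline(slope = c(Z95, -Z95), intercept = 0,
                         linetype = "dotted", colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$mu, colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Standard error", y = "log HR",
      title = "Negative-control estimates and fitted empirical null",
      subtitle = sprintf("mu = %.3f, tau = %.3f (%d controls)",
                         object$mu, object$tau, object$n_controls)
    ) +
    ggplot2::theme_minimal()
}
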