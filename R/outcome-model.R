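#' Fit a Cox model conditioned on propensity strata
#'
#' Estimates the target-vs-comparator hazard ratio by maximizing the
#' stratified partial likelihood (separate baseline hazard per propensity
#' stratum, Efron tie handling -- integer-day data guarantees ties). No
#' covariates beyond the stratification enter the model. When either arm
#' has zero events the hazard ratio is inestimable and an exclusion record
#' is returned instead, mirroring the zero-event exclusion rule; the same
#' happens on separation or non-convergence.
#'
#' @param risk_intervals Tibble from [compute_time_at_risk()] (`arm`,
#'   `event`, `person_days`).
#' @param strata Integer stratum assignment aligned with the rows of
#'   `risk_intervals` (or a column name in it).
#' @param analysis_id Optional label carried into the result.
#' @return One-row tibble (an estimation result): `analysis_id`, `log_hr`,
#'   `se_log_hr`, `hr`, `ci95_low`, `ci95_high`, `p_two_sided`,
#'   `events_target`, `events_comparator`, `persondays_target`,
#'   `persondays_comparator`, `excluded`, `reason`.
#' @export
fit_stratified_cox <- function(risk_intervals, strata,
                               analysis_id = NA_character_) {
  d <- tibble::as_tibble(risk_intervals)
  if (is.character(strata) && length(strata) == 1L) {
    strata <- d[[strata]]
  }
  stopifnot(length(strata) == nrow(d))
  d$stratum <- strata
  d$trt <- as.integer(d$arm == "target")

  ev_t <- sum(d$event[d$trt == 1L])
  ev_c <- sum(d$event[d$trt == 0L])
  pd_t <- sum(d$person_days[d$trt == 1L])
  pd_c <- sum(d$person_days[d$trt == 0L])
  base <- tibble::tibble(
    analysis_id = analysis_id, log_hr = NA_real_, se_log_hr = NA_real_,
    hr = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
    p_two_sided = NA_real_, events_target = ev_t, events_comparator = ev_c,
    persondays_target = pd_t, persondays_comparator = pd_c,
    excluded = TRUE, reason = NA_character_
  )
  if (ev_t == 0L || ev_c == 0L) {
    base$reason <- "zero events in at least one arm"
    return(base)
  }

  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(
        survival::Surv(person_days, event) ~ trt +
          survival::strata(stratum),
        data = d, ties = "efron",
        control = survival::coxph.control(eps = 1e-9, iter.max = 100)
      ),
      warning = function(w) {
        if (grepl("infinite|converge|beta may", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) NULL
  )
  beta <- if (!is.null(fit)) unname(coef(fit)[1]) else NA_real_
  se <- if (!is.null(fit)) sqrt(fit$var[1, 1]) else NA_real_
  if (is.null(fit) || !is.finite(beta) || !is.finite(se) ||
      abs(beta) > 20) {
    base$reason <- "separation/nonconvergence"
    return(base)
  }
  base |>
    dplyr::mutate(
      log_hr = beta, se_log_hr = se, hr = exp(beta),
      ci95_low = exp(beta - Z95 * se), ci95_high = exp(beta + Z95 * se),
      p_two_sided = 2 * pnorm(-abs(beta / se)),
      excluded = FALSE
    )
}

#' Incidence rate per 1000 person-years
#'
#' @param events Event count(s).
#' @param person_days Person-time in days.
#' @return `events / (person_days / 365.25) * 1000`; zero events with zero
#'   person-time give 0.
#' @export
#' @examples
#' incidence_rate(10, 1000 * 365.25) # 10 per 1000 person-years
incidence_rate <- function(events, person_days) {
  if (any(events < 0) || any(person_days < 0)) {
    abort("`events` and `person_days` must be non-negative.",
          class = "safetysignal_data_error")
  }
  if (any(person_days == 0 & events > 0)) {
    abort("events observed with zero person-time.",
          class = "safetysignal_data_error")
  }
  ifelse(person_days == 0, 0, events / (person_days / 365.25) * 1000)
}

#' Minimum detectable relative risk
#'
#' Two-sided normal-approximation power calculation: with `events_total`
#' events split between arms in proportion to person-time, the standard
#' error of the log relative risk under the null is
#' `sqrt(1/(E p) + 1/(E (1-p)))` with `p` the exposed person-time
#' fraction, and the smallest detectable relative risk at the given alpha
#' and power is `exp((z_{1-alpha/2} + z_{power}) * se)`.
#'
#' @param events_total Total expected events across both arms.
#' @param ratio_persontime Exposed:unexposed person-time ratio (default 1).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @return The MDRR (> 1); `Inf` at zero events.
#' @export
minimum_detectable_rr <- function(events_total, ratio_persontime = 1,
                                  alpha = 0.05, power = 0.8) {
  stopifnot(events_total >= 0, ratio_persontime > 0)
  if (events_total == 0) return(Inf)
  p <- ratio_persontime / (1 + ratio_persontime)
  se <- sqrt(1 / (events_total * p) + 1 / (events_total * (1 - p)))
  exp((qnorm(1 - alpha / 2) + qnorm(power)) * se)
}
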