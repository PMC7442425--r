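#' Heterogeneity statistics with the I-squared gate
#'
#' Cochran's Q against the inverse-variance fixed-effects mean,
#' `I^2 = max(0, (Q - df)/Q)`, and the DerSimonian-Laird moment estimator
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` -- the
#' construction that estimates across-database variance by comparing each
#' database-specific result with a fixed-effects meta-analysis. The gate
#' flags `I^2 >= gate` (default 0.4): gated drug--outcome pairs get no
#' pooled estimate.
#'
#' @param log_hr,se Per-database estimates and standard errors (log scale).
#' @param gate I-squared threshold at or above which pooling is withheld.
#' @return One-row tibble: `Q`, `df`, `i_squared`, `tau_squared`, `gated`.
#' @export
#' @examples
#' heterogeneity(c(0, 1), c(0.5, 0.5)) # Q = 2, I^2 = 0.5, tau^2 = 0.25
heterogeneity <- function(log_hr, se, gate = 0.4) {
  if (any(se <= 0) || any(!is.finite(se))) {
    abort("standard errors must be positive and finite.",
          class = "safetysignal_data_error")
  }
  k <- length(log_hr)
  if (k == 1L) {
    return(tibble::tibble(Q = 0, df = 0L, i_squared = 0,
                          tau_squared = 0, gated = FALSE))
  }
  w <- 1 / se^2
  fixed <- sum(w * log_hr) / sum(w)
  Q <- sum(w * (log_hr - fixed)^2)
  df <- k - 1L
  i2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  tibble::tibble(Q = Q, df = df, i_squared = i2, tau_squared = tau2,
                 gated = i2 >= gate)
}

#' Random-effects pooled estimate
#'
#' Inverse-variance pooling with weights `1/(se_i^2 + tau^2)`. Refuses
#' gated input: when the heterogeneity gate has fired no pooled estimate
#' exists, mirroring the handling of drug--outcome pairs with
#' `I^2 >= 0.4`.
#'
#' @inheritParams heterogeneity
#' @param labels Optional per-database labels (kept for forest plots).
#' @return Object of class `meta_result` (a one-row tibble with
#'   `pooled_log_hr`, `pooled_se`, `pooled_hr`, `ci95_low`, `ci95_high`,
#'   `p_two_sided`, `k`, plus the [heterogeneity()] columns). The
#'   per-database estimates are attached as attribute `estimates`. Gated
#'   input produces a row with `gated = TRUE` and `NA` pooled fields via
#'   [meta_analysis()]; calling `random_effects_pool()` on it directly is
#'   an error.
#' @export
random_effects_pool <- function(log_hr, se, gate = 0.4, labels = NULL) {
  het <- heterogeneity(log_hr, se, gate = gate)
  if (het$gated) {
    abort(sprintf(
      "I-squared = %.2f >= %.2f: pooling is gated; no pooled estimate.",
      het$i_squared, gate), class = "safetysignal_gate_error")
  }
  w <- 1 / (se^2 + het$tau_squared)
  pooled <- sum(w * log_hr) / sum(w)
  pse <- sqrt(1 / sum(w))
  out <- dplyr::bind_cols(
    tibble::tibble(
      pooled_log_hr = pooled, pooled_se = pse, pooled_hr = exp(pooled),
      ci95_low = exp(pooled - Z95 * pse),
      ci95_high = exp(pooled + Z95 * pse),
      p_two_sided = 2 * pnorm(-abs(pooled / pse)),
      k = length(log_hr)
    ),
    het
  )
  class(out) <- c("meta_result", class(out))
  attr(out, "estimates") <- tibble::tibble(
    label = labels %||% paste0("db", seq_along(log_hr)),
    log_hr = log_hr, se = se
  )
  out
}

#' Gated random-effects meta-analysis
#'
#' Computes heterogeneity and, unless the I-squared gate fires, the
#' random-effects pooled estimate. Gated pairs return a `meta_result` row
#' with `gated = TRUE` and `NA` pooled fields, so reports can state that a
#' summary estimate was withheld.
#'
#' @param estimates Tibble with columns `log_hr`, `se` and optionally
#'   `label` (one row per database). Rows flagged `excluded`, if the
#'   column is present, are dropped first.
#' @param gate I-squared gate (default 0.4).
#' @param variance_inflation Multiplier (>= 1) on the pooled variance; a
#'   crude guard for overlapping source populations, default 1.
#' @return A `meta_result` (see [random_effects_pool()]).
#' @export
meta_analysis <- function(estimates, gate = 0.4, variance_inflation = 1) {
  if ("excluded" %in% names(estimates)) {
    estimates <- dplyr::filter(estimates, !.data$excluded)
  }
  labels <- if ("label" %in% names(estimates)) {
    estimates$label
  } else {
    paste0("db", seq_len(nrow(estimates)))
  }
  het <- heterogeneity(estimates$log_hr, estimates$se, gate = gate)
  if (het$gated) {
    out <- dplyr::bind_cols(
      tibble::tibble(pooled_log_hr = NA_real_, pooled_se = NA_real_,
                     pooled_hr = NA_real_, ci95_low = NA_real_,
                     ci95_high = NA_real_, p_two_sided = NA_real_,
                     k = nrow(estimates)),
      het
    )
    class(out) <- c("meta_result", class(out))
    attr(out, "estimates") <- tibble::tibble(
      label = labels, log_hr = estimates$log_hr, se = estimates$se
    )
    return(out)
  }
  out <- random_effects_pool(estimates$log_hr, estimates$se, gate = gate,
                             labels = labels)
  if (variance_inflation != 1) {
    out$pooled_se <- out$pooled_se * sqrt(variance_inflation)
    out$ci95_low <- exp(out$pooled_log_hr - Z95 * out$pooled_se)
    out$ci95_high <- exp(out$pooled_log_hr + Z95 * out$pooled_se)
    out$p_two_sided <- 2 * pnorm(-abs(out$pooled_log_hr / out$pooled_se))
  }
  out
}

#' @rdname meta_analysis
#' @param x A `meta_result`.
#' @param ... Unused.
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) tibble::as_tibble(x)

#' Forest-plot data: one row per database plus a pooled row when not gated
#'
#' @param x A `meta_result`.
#' @return Tibble with `label`, `hr`, `ci95_low`, `ci95_high`, `pooled`.
#' @export
forest_data <- function(x) {
  stopifnot(inherits(x, "meta_result"))
  est <- attr(x, "estimates")
  rows <- tibble::tibble(
    label = est$label, hr = exp(est$log_hr),
    ci95_low = exp(est$log_hr - Z95 * est$se),
    ci95_high = exp(est$log_hr + Z95 * est$se),
    pooled = FALSE
  )
  if (!x$gated) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      label = "Pooled", hr = x$pooled_hr, ci95_low = x$ci95_low,
      ci95_high = x$ci95_high, pooled = TRUE
    ))
  }
  rows
}

#' Pool per-database user counts, event counts and incidence rates
#'
#' Reproduces meta-analysis table rows: user and event totals are sums;
#' the pooled incidence rate is total events divided by total person-time,
#' with person-time back-derived as `events / rate` when only counts and
#' rates are available. Masked cells (printed as `"<n"`) propagate: a
#' masked event count contributes its bound, the total is then itself a
#' bound displayed as `"<sum"`, and the pooled rate computed from it is
#' displayed as a `"<"` bound.
#'
#' @param per_database Tibble with columns `users_t`, `users_c`,
#'   `events_t`, `events_c`, `rate_t`, `rate_c` (rates per 1000
#'   person-years; event columns may be numeric or character with `"<n"`
#'   cells) and optionally `database`.
#' @return One-row tibble with totals, pooled rates, their display strings
#'   and masking flags.
#' @export
pool_counts_and_rates <- function(per_database) {
  d <- tibble::as_tibble(per_database)
  side <- function(ev_col, rate_col) {
    ev <- parse_masked_count(d[[ev_col]])
    rate <- parse_masked_count(d[[rate_col]])
    if (any(ev$value > 0 & rate$value == 0)) {
      abort("events > 0 with rate 0: person-time unrecoverable.",
            class = "safetysignal_data_error")
    }
    pt <- ifelse(ev$value == 0, 0, ev$value / rate$value) # 1000-PY units
    total_ev <- sum(ev$value)
    masked <- any(ev$masked)
    pooled_rate <- if (sum(pt) > 0) total_ev / sum(pt) else 0
    list(events = total_ev, events_masked = masked,
         events_display = if (masked) paste0("<", total_ev)
                          else as.character(total_ev),
         rate = pooled_rate, rate_masked = masked,
         rate_display = if (masked) paste0("<", format_rate(pooled_rate))
                        else format_rate(pooled_rate))
  }
  st <- side("events_t", "rate_t")
  sc <- side("events_c", "rate_c")
  tibble::tibble(
    users_t = sum(d$users_t), users_c = sum(d$users_c),
    events_t = st$events, events_t_masked = st$events_masked,
    events_t_display = st$events_display,
    events_c = sc$events, events_c_masked = sc$events_masked,
    events_c_display = sc$events_display,
    rate_t = st$rate, rate_t_display = st$rate_display,
    rate_c = sc$rate, rate_c_display = sc$rate_display
  )
}

#' Mask small cell counts
#'
#' Counts of 1 to `threshold - 1` are displayed as `"<threshold"` to
#' minimise re-identification risk; zero stays `"0"` (zero-event analyses
#' are excluded upstream) and counts at or above the threshold are shown
#' as-is.
#'
#' @param raw Non-negative integer count(s).
#' @param threshold Masking threshold (default 5).
#' @return Tibble with `raw` and `display`.
#' @export
#' @examples
#' mask_small_counts(c(0, 3, 5))$display # "0" "<5" "5"
mask_small_counts <- function(raw, threshold = 5) {
  stopifnot(all(raw >= 0))
  tibble::tibble(
    raw = raw,
    display = dplyr::case_when(
      raw >= threshold | raw == 0 ~ as.character(raw),
      TRUE ~ paste0("<", threshold)
    )
  )
}

#' Display an incidence rate computed from a possibly-masked count
#'
#' When the event count is masked, the rate computed from the real count
#' would re-identify it, so the displayed rate is the upper bound obtained
#' from the masking threshold over the same person-time.
#'
#' @param events Raw event count.
#' @param person_days Person-time in days.
#' @param threshold Masking threshold (default 5).
#' @return Display string, e.g. `"3.85"` or `"<3.54"`.
#' @export
masked_rate <- function(events, person_days, threshold = 5) {
  stopifnot(length(events) == length(person_days))
  rate <- incidence_rate(pmax(events, 0), person_days)
  bound <- incidence_rate(rep(threshold, length(events)), person_days)
  ifelse(events > 0 & events < threshold,
         paste0("<", format_rate(bound)), format_rate(rate))
}

parse_masked_count <- function(x) {
  if (is.numeric(x)) {
    return(tibble::tibble(value = as.numeric(x),
                          masked = rep(FALSE, length(x))))
  }
  x <- trimws(as.character(x))
  masked <- startsWith(x, "<")
  val <- suppressWarnings(as.numeric(sub("^<", "", x)))
  if (any(is.na(val))) {
    abort("unparseable count cell(s).", class = "safetysignal_data_error")
  }
  tibble::tibble(value = val, masked = masked)
}

format_rate <- function(x) formatC(x, format = "f", digits = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
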