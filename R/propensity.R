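#' Fit the large-scale regularized propensity model
#'
#' Logistic regression of target-drug initiation on all baseline
#' covariates, fitted with a LASSO penalty; the penalty is chosen by
#' ten-fold cross-validation (out-of-fold binomial deviance) over a
#' 20-point logarithmic, data-driven grid. Fold assignment is seeded, so
#' the selected penalty and the scores are reproducible.
#'
#' @param covariates Data frame (or matrix) of numeric baseline covariates,
#'   one row per person.
#' @param arm Vector with levels/values `"target"` and `"comparator"`
#'   aligned with the rows of `covariates`.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `ps_model`: coefficients at the selected
#'   penalty, the penalty itself, and per-person scores (probability of
#'   target) in (0, 1). Supports [tidy()][generics::tidy] and
#'   [glance()][generics::glance]-style accessors via `tidy.ps_model()` /
#'   `glance.ps_model()`.
#' @export
fit_propensity_model <- function(covariates, arm, folds = 10, seed = 1) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  y <- as.integer(arm == "target")
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    abort("need at least two persons in each arm.",
          class = "safetysignal_estimation_error")
  }
  if (!all(is.finite(x))) {
    abort("covariate matrix must be finite.",
          class = "safetysignal_data_error")
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = 20,
                          type.measure = "deviance",
                          standardize = TRUE)
  lambda <- cv$lambda.min
  scores <- as.numeric(predict(cv, newx = x, s = lambda,
                               type = "response"))
  if (any(scores < 1e-10 | scores > 1 - 1e-10)) {
    warn(paste("propensity scores at the machine boundary suggest",
               "(near-)separation; falling back to the largest penalty."))
    lambda <- max(cv$lambda)
    scores <- as.numeric(predict(cv, newx = x, s = lambda,
                                 type = "response"))
  }
  eps <- 1e-10
  scores <- pmin(pmax(scores, eps), 1 - eps)
  cf <- as.matrix(coef(cv, s = lambda))
  structure(
    list(
      coefficients = stats::setNames(cf[-1, 1], rownames(cf)[-1]),
      intercept = cf[1, 1],
      selected_penalty = lambda,
      cv_folds = folds,
      scores = scores,
      n = nrow(x),
      target_share = mean(y)
    ),
    class = "ps_model"
  )
}

#' @export
print.ps_model <- function(x, ...) {
  cat("<ps_model>  n =", x$n, " lambda =", signif(x$selected_penalty, 4),
      " nonzero coefficients =", sum(x$coefficients != 0), "\n")
  invisible(x)
}

#' Tidy a propensity model
#'
#' @param x A `ps_model`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (log-odds scale, intercept
#'   included).
#' @method tidy ps_model
#' @export
tidy.ps_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row summary of a propensity model
#'
#' @inheritParams tidy.ps_model
#' @return Tibble with the selected penalty, number of non-zero
#'   coefficients, sample size, folds and target share.
#' @method glance ps_model
#' @export
glance.ps_model <- function(x, ...) {
  tibble::tibble(
    selected_penalty = x$selected_penalty,
    n_nonzero = sum(x$coefficients != 0),
    n = x$n, cv_folds = x$cv_folds, target_share = x$target_share
  )
}

#' Assign propensity-score quintile strata
#'
#' Cuts the pooled score distribution at its 20/40/60/80 percentiles.
#' Tied scores are assigned by the (right-closed) interval they fall in;
#' if every score is identical the quantile breaks collapse and all
#' persons land in stratum 1 with a warning.
#'
#' @param scores Numeric propensity scores.
#' @param n_strata Number of strata (default 5 quintiles).
#' @return Integer stratum assignment in `1:n_strata` per person.
#' @export
stratify_by_quintile <- function(scores, n_strata = 5) {
  if (length(scores) < n_strata) {
    abort("fewer persons than strata.",
          class = "safetysignal_estimation_error")
  }
  br <- quantile(scores, probs = seq(0, 1, length.out = n_strata + 1),
                 type = 7, names = FALSE)
  ubr <- unique(br)
  if (length(ubr) < 2L) {
    warn("all propensity scores identical; one stratum assigned.")
    return(rep(1L, length(scores)))
  }
  if (length(ubr) < length(br)) {
    warn("tied quantile breaks; fewer effective strata than requested.")
  }
  as.integer(cut(scores, breaks = ubr, include.lowest = TRUE,
                 right = TRUE))
}

#' Standardized mean difference
#'
#' `(mean_t - mean_c) / sqrt((var_t + var_c) / 2)` with population
#' variances, so a binary covariate with prevalences p and q gives exactly
#' `(p - q) / sqrt((p(1-p) + q(1-q))/2)`. With strata supplied, the
#' numerator becomes the stratum-size-weighted (both arms combined) mean of
#' within-stratum arm differences while the denominator keeps the crude
#' variances, the usual post-stratification balance metric.
#'
#' @param values Numeric covariate values for all persons.
#' @param arm Arm labels aligned with `values` (`"target"`/`"comparator"`).
#' @param strata Optional stratum assignment for the after-stratification
#'   version.
#' @return Signed SMD; `Inf` (with a warning) when the pooled variance is
#'   zero but means differ, 0 when both are zero.
#' @export
#' @examples
#' x <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
#' a <- rep(c("target", "comparator"), each = 100)
#' standardized_mean_difference(x, a) # 0.2325
standardized_mean_difference <- function(values, arm, strata = NULL) {
  t_idx <- arm == "target"
  c_idx <- arm == "comparator"
  if (!any(t_idx) || !any(c_idx)) {
    abort("need at least one value per arm.",
          class = "safetysignal_data_error")
  }
  pvar <- function(v) mean((v - mean(v))^2)
  vt <- pvar(values[t_idx])
  vc <- pvar(values[c_idx])
  denom <- sqrt((vt + vc) / 2)

  if (is.null(strata)) {
    num <- mean(values[t_idx]) - mean(values[c_idx])
  } else {
    d <- tibble::tibble(v = values, t = t_idx, s = strata) |>
      dplyr::group_by(.data$s) |>
      dplyr::summarise(
        w = dplyr::n(),
        diff = mean(.data$v[.data$t]) - mean(.data$v[!.data$t]),
        both = any(.data$t) && any(!.data$t),
        .groups = "drop"
      )
    d <- d[d$both, ]
    if (!nrow(d)) {
      abort("no stratum contains both arms.",
            class = "safetysignal_data_error")
    }
    num <- sum(d$w * d$diff) / sum(d$w)
  }
  if (denom == 0) {
    if (num == 0) return(0)
    warn("zero pooled variance with unequal means; SMD is infinite.")
    return(sign(num) * Inf)
  }
  num / denom
}

#' Covariate balance report
#'
#' Computes before- and after-stratification standardized mean differences
#' for every covariate column and applies the |SMD| <= `threshold` rule
#' (0.1 flags non-negligible imbalance): `pass` is `TRUE` only when every
#' post-stratification |SMD| is at or below the threshold, and a failing
#' report is the signal for the pipeline to exclude that analysis.
#'
#' @param covariates Data frame of numeric covariates.
#' @param arm Arm labels per person.
#' @param strata Stratum assignment per person.
#' @param threshold Balance threshold on |SMD| (default 0.1).
#' @return A `balance_report`: tibble with one row per covariate
#'   (`covariate`, `mean_target`, `mean_comparator`, `smd_before`,
#'   `smd_after`) and attributes `max_abs_smd_after`, `pass`, `threshold`.
#' @export
balance_report <- function(covariates, arm, strata, threshold = 0.1) {
  covariates <- tibble::as_tibble(covariates)
  if (ncol(covariates) == 0L) {
    warn("empty covariate set; balance passes vacuously.")
    out <- tibble::tibble(covariate = character(), mean_target = double(),
                          mean_comparator = double(),
                          smd_before = double(), smd_after = double())
    attr(out, "max_abs_smd_after") <- 0
    attr(out, "pass") <- TRUE
    attr(out, "threshold") <- threshold
    class(out) <- c("balance_report", class(out))
    return(out)
  }
  t_idx <- arm == "target"
  out <- purrr::map_dfr(names(covariates), function(nm) {
    v <- covariates[[nm]]
    tibble::tibble(
      covariate = nm,
      mean_target = mean(v[t_idx]),
      mean_comparator = mean(v[!t_idx]),
      smd_before = standardized_mean_difference(v, arm),
      smd_after = standardized_mean_difference(v, arm, strata)
    )
  })
  attr(out, "max_abs_smd_after") <- max(abs(out$smd_after))
  attr(out, "pass") <- all(abs(out$smd_after) <= threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("balance_report", class(out))
  out
}

#' One-row summary of a balance report
#'
#' @param x A `balance_report`.
#' @param ... Unused.
#' @return Tibble with `n_covariates`, `max_abs_smd_before`,
#'   `max_abs_smd_after`, `pass`.
#' @method glance balance_report
#' @export
glance.balance_report <- function(x, ...) {
  tibble::tibble(
    n_covariates = nrow(x),
    max_abs_smd_before = if (nrow(x)) max(abs(x$smd_before)) else 0,
    max_abs_smd_after = attr(x, "max_abs_smd_after"),
    pass = attr(x, "pass")
  )
}

#' Equipoise diagnostic on the preference-score scale
#'
#' Transforms propensity scores to preference scores (adjusting for the
#' target share) and reports the fraction of each arm inside the 0.3--0.7
#' band. Reported for eyeballing only; it never gates an analysis.
#'
#' @param scores Propensity scores.
#' @param arm Arm labels.
#' @return Tibble with per-arm equipoise fractions.
#' @export
equipoise <- function(scores, arm) {
  p <- mean(arm == "target")
  pref <- plogis(qlogis_safe(scores) - log(p / (1 - p)))
  tibble::tibble(
    arm = c("target", "comparator"),
    in_equipoise = c(mean(pref[arm == "target"] >= 0.3 &
                            pref[arm == "target"] <= 0.7),
                     mean(pref[arm == "comparator"] >= 0.3 &
                            pref[arm == "comparator"] <= 0.7))
  )
}

qlogis_safe <- function(p) {
  eps <- 1e-12
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}
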