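#' Run the full cohort estimation pipeline on one database
#'
#' Chains the stages for a single database: new-user cohort construction,
#' baseline covariate extraction, LASSO propensity model, quintile
#' stratification, balance diagnostics, stratified Cox estimation for
#' every study and negative-control outcome under the given time-at-risk,
#' empirical-null fitting from the negative controls, and calibration of
#' the study estimates. Analyses with zero events in an arm are excluded
#' by the Cox stage; a failed balance diagnostic (max |SMD| after
#' stratification above the threshold) excludes every estimate from the
#' database, mirroring the diagnostic gate.
#'
#' @param db A `claims_db` (simulated or read from disk with ground-truth
#'   metadata naming outcome and negative-control codes, unless given
#'   explicitly).
#' @param outcome_codes Study outcome condition codes.
#' @param nc_codes Negative-control outcome codes.
#' @param target_code,comparator_code,indication_code Cohort definition.
#' @param tar A [tar_spec()].
#' @param balance_threshold |SMD| gate after stratification (default 0.1).
#' @param min_controls Floor for the empirical null (default 5).
#' @param seed Seed for the propensity-model fold split.
#' @return Object of class `cohort_analysis`: list with `results`
#'   (calibrated study-outcome rows), `nc_results`, `null`, `balance`,
#'   `ps`, `cohort`, `excluded_all`.
#' @export
run_cohort_analysis <- function(db,
                                outcome_codes = db$truth$outcome_codes,
                                nc_codes = db$truth$negative_control_codes,
                                target_code =
                                  db$truth$config$target_code,
                                comparator_code =
                                  db$truth$config$comparator_code,
                                indication_code =
                                  db$truth$config$indication_code,
                                tar = tar_spec("intention_to_treat"),
                                balance_threshold = 0.1,
                                min_controls = 5,
                                seed = 1) {
  cohort <- select_new_users(db, target_code, comparator_code,
                             indication_code = indication_code,
                             max_gap_days = tar$era_gap_days)
  all_outcomes <- c(outcome_codes, nc_codes)
  cov <- add_baseline_covariates(cohort, db,
                                 exclude_codes = c(all_outcomes,
                                                   indication_code))
  cov_cols <- c("age_at_index", "female",
                setdiff(names(cov), names(cohort)))
  ps <- fit_propensity_model(cov[cov_cols], cov$arm, seed = seed)
  strata <- stratify_by_quintile(ps$scores)
  bal <- balance_report(cov[cov_cols], cov$arm, strata,
                        threshold = balance_threshold)
  excluded_all <- !attr(bal, "pass")

  eras <- build_drug_eras(
    dplyr::filter(db$drug_exposures,
                  .data$drug_code %in% c(target_code, comparator_code)),
    max_gap_days = tar$era_gap_days
  )
  strata_by_person <- stats::setNames(strata, cohort$person_id)

  fit_one <- function(code, gate_balance) {
    ev <- dplyr::filter(db$condition_occurrences,
                        .data$condition_code == code)
    ri <- compute_time_at_risk(cohort, eras, ev, tar,
                               db$observation_periods)
    res <- fit_stratified_cox(
      ri, strata_by_person[as.character(ri$person_id)],
      analysis_id = code
    )
    if (gate_balance && excluded_all && !res$excluded) {
      res$excluded <- TRUE
      res$reason <- "covariate imbalance after stratification"
    }
    res
  }
  study <- purrr::map_dfr(outcome_codes, fit_one, gate_balance = TRUE)
  # negative controls are diagnostics: the empirical null is still fitted
  # (and reported) when balance fails, but study estimates stay excluded
  ncs <- purrr::map_dfr(nc_codes, fit_one, gate_balance = FALSE)

  usable <- dplyr::filter(ncs, !.data$excluded)
  null <- fit_empirical_null(usable$log_hr, usable$se_log_hr,
                             min_controls = min_controls)
  structure(
    list(
      results = calibrate_results(study, null),
      nc_results = calibrate_results(ncs, null),
      null = null,
      balance = bal,
      ps = ps,
      cohort = cohort,
      excluded_all = excluded_all
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  cat("  cohort:", nrow(x$cohort), "persons (",
      sum(x$cohort$arm == "target"), "target )\n")
  cat("  balance: max |SMD| after =",
      signif(attr(x$balance, "max_abs_smd_after"), 3),
      if (attr(x$balance, "pass")) "(pass)" else "(FAIL - excluded)", "\n")
  if (!is.null(x$null)) {
    cat(sprintf("  empirical null: mu = %.3f, tau = %.3f (%d controls)\n",
                x$null$mu, x$null$tau, x$null$n_controls))
  }
  cat("  study outcomes:", nrow(x$results), "(",
      sum(x$results$excluded), "excluded )\n")
  invisible(x)
}

#' Pool one outcome across a network of database analyses
#'
#' Collects the (calibrated, when available) estimate for `outcome_code`
#' from each `cohort_analysis`, drops excluded rows, and runs the gated
#' random-effects meta-analysis. Calibrated estimates are pooled when
#' every database has them, matching a per-database-calibrate-then-pool
#' flow.
#'
#' @param analyses Named list of `cohort_analysis` objects (names become
#'   database labels).
#' @param outcome_code The study outcome to pool.
#' @param use_calibrated Pool calibrated estimates when available
#'   (default `TRUE`).
#' @param gate I-squared gate (default 0.4).
#' @return A `meta_result`.
#' @export
pool_network <- function(analyses, outcome_code, use_calibrated = TRUE,
                         gate = 0.4) {
  rows <- purrr::imap_dfr(analyses, function(a, nm) {
    r <- dplyr::filter(a$results, .data$analysis_id == outcome_code)
    if (!nrow(r)) return(NULL)
    cal_ok <- use_calibrated && isTRUE(r$calibrated[1])
    tibble::tibble(
      label = nm,
      log_hr = if (cal_ok) r$calibrated_log_hr[1] else r$log_hr[1],
      se = if (cal_ok) r$calibrated_se[1] else r$se_log_hr[1],
      excluded = r$excluded[1]
    )
  })
  meta_analysis(rows, gate = gate)
}
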