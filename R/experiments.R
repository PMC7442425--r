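#' Hazard-ratio recovery experiment
#'
#' Repeatedly simulates a confounded new-user cohort with a known true
#' hazard ratio and estimates it with the full adjustment chain: LASSO
#' propensity model on the measured baseline covariates, quintile
#' stratification, and Cox regression conditioned on the strata under a
#' 30-day intention-to-treat window. The mean of the estimated log hazard
#' ratios measures how much confounding the design removes.
#'
#' The confounding structure is the generator default: treatment choice
#' driven by sex, lupus, psoriasis, Crohn's disease, heart disease and
#' diabetes, with lupus, heart disease, sex and diabetes also moving the
#' outcome hazard.
#'
#' @param reps Number of simulation replicates.
#' @param n Persons per replicate.
#' @param true_hr True target-vs-comparator hazard ratio.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @return Tibble with one row per replicate: `rep`, `log_hr`, `se`,
#'   `excluded`.
#' @export
hr_recovery_experiment <- function(reps = 50, n = 20000, true_hr = 2,
                                   seed = 1) {
  purrr::map_dfr(seq_len(reps), function(r) {
    cfg <- sim_config(
      n_persons = n, seed = (seed * 1000 + r) %% .Machine$integer.max,
      outcomes = list(cv_event = list(
        baseline_hazard = 1e-3, log_hr = log(true_hr),
        covariate_effects = c(sle = 0.7, heart_disease = 0.9,
                              female = -0.3, diabetes = 0.4)
      )),
      n_negative_controls = 0
    )
    db <- simulate_claims(cfg)
    res <- ps_stratified_cox(db, seed = seed + r)
    tibble::tibble(rep = r, log_hr = res$log_hr, se = res$se_log_hr,
                   excluded = res$excluded)
  })
}

#' PS-stratified Cox estimate for the first study outcome of a database
#'
#' Convenience chain used by the recovery experiment and examples:
#' new-user cohort, baseline covariates, LASSO propensity model, quintile
#' strata, stratified Cox on the 30-day intention-to-treat window. The
#' balance gate is reported but not enforced here; use
#' [run_cohort_analysis()] for the gated pipeline.
#'
#' @param db A simulated `claims_db`.
#' @param outcome_code Outcome to estimate (default: the first study
#'   outcome recorded in the ground truth).
#' @param tar A [tar_spec()].
#' @param seed Seed for the propensity fold split.
#' @return One-row estimation-result tibble (see [fit_stratified_cox()]).
#' @export
ps_stratified_cox <- function(db,
                              outcome_code = db$truth$outcome_codes[1],
                              tar = tar_spec("intention_to_treat"),
                              seed = 1) {
  cfg <- db$truth$config
  coh <- select_new_users(db, cfg$target_code, cfg$comparator_code,
                          indication_code = cfg$indication_code)
  cov <- add_baseline_covariates(
    coh, db,
    exclude_codes = c(db$truth$outcome_codes,
                      db$truth$negative_control_codes,
                      cfg$indication_code)
  )
  cov_cols <- c("age_at_index", "female",
                setdiff(names(cov), names(coh)))
  ps <- fit_propensity_model(cov[cov_cols], cov$arm, seed = seed)
  strata <- suppressWarnings(stratify_by_quintile(ps$scores))
  eras <- build_drug_eras(db$drug_exposures)
  ev <- dplyr::filter(db$condition_occurrences,
                      .data$condition_code == outcome_code)
  ri <- compute_time_at_risk(coh, eras, ev, tar, db$observation_periods)
  st <- stats::setNames(strata, coh$person_id)
  fit_stratified_cox(ri, st[as.character(ri$person_id)],
                     analysis_id = outcome_code)
}

#' Incidence-rate-ratio recovery experiment for the case series
#'
#' Repeatedly simulates recurrent-event data with a known true incidence
#' rate ratio and per-person exposure eras, builds the self-controlled
#' intervals, and fits the conditional Poisson model (exposure only). The
#' mean estimated log IRR measures the within-person design's recovery.
#'
#' @param reps Replicates.
#' @param n Persons per replicate (sized so roughly 500 become cases).
#' @param true_irr True incidence rate ratio during exposure.
#' @param seed Base seed.
#' @return Tibble with `rep`, `log_irr`, `se`, `n_cases`.
#' @export
sccs_recovery_experiment <- function(reps = 20, n = 1250, true_irr = 2,
                                     seed = 1) {
  purrr::map_dfr(seq_len(reps), function(r) {
    sim <- simulate_sccs_data(
      n_persons = n, obs_days = 730, baseline_rate = 6e-4,
      irr = true_irr, seed = (seed * 1000 + r) %% .Machine$integer.max
    )
    iv <- build_sccs_intervals(sim$observation_periods, sim$eras,
                               sim$events, seasons = FALSE,
                               age_band_years = NULL)
    fit <- fit_sccs(iv, regularize_covariates = FALSE)
    tibble::tibble(rep = r, log_irr = fit$log_irr, se = fit$se,
                   n_cases = fit$n_cases)
  })
}

#' Type-I-error restoration experiment
#'
#' Draws negative-control estimates whose true effect is null but whose
#' observed log hazard ratios carry systematic error
#' `Normal(mu, tau^2)` on top of their sampling error, then measures the
#' fraction of controls declared significant (p < 0.05) before and after
#' empirical calibration, and the recovered null parameters.
#'
#' @param reps Replicates.
#' @param n_controls Negative controls per replicate.
#' @param mu,tau Injected systematic-error mean and spread (log scale).
#' @param seed Base seed.
#' @return Tibble with `rep`, `uncalibrated_rate`, `calibrated_rate`,
#'   `mu_hat`, `tau_hat`.
#' @export
calibration_experiment <- function(reps = 20, n_controls = 40,
                                   mu = 0.25, tau = 0.05, seed = 1) {
  purrr::map_dfr(seq_len(reps), function(r) {
    set.seed((seed * 1000 + r) %% .Machine$integer.max)
    se <- runif(n_controls, 0.08, 0.15)
    est <- rnorm(n_controls, mu, tau) + rnorm(n_controls, 0, se)
    null <- fit_empirical_null(est, se)
    tibble::tibble(
      rep = r,
      uncalibrated_rate = mean(2 * pnorm(-abs(est / se)) < 0.05),
      calibrated_rate = mean(calibrate_p(est, se, null) < 0.05),
      mu_hat = null$mu,
      tau_hat = null$tau
    )
  })
}
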