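# Small configurations reused across tests.

# no confounding at all: treatment is a fair coin, outcome ignores covariates
null_config <- function(n = 2000, seed = 1, log_hr = 0,
                        baseline_hazard = 1e-3, n_nc = 0) {
  sim_config(
    n_persons = n, seed = seed,
    treatment_intercept = 0,
    treatment_coefs = c(female = 0),
    outcomes = list(y = list(baseline_hazard = baseline_hazard,
                             log_hr = log_hr,
                             covariate_effects = NULL)),
    n_negative_controls = n_nc
  )
}

# the confounded recovery scenario: measured confounders move both
# treatment choice and outcome hazard
confounded_config <- function(n = 20000, seed = 1, log_hr = log(2),
                              n_nc = 0) {
  sim_config(
    n_persons = n, seed = seed,
    outcomes = list(cv_event = list(
      baseline_hazard = 1e-3, log_hr = log_hr,
      covariate_effects = c(sle = 0.7, heart_disease = 0.9,
                            female = -0.3, diabetes = 0.4)
    )),
    n_negative_controls = n_nc
  )
}

# one PS-stratified Cox estimate for the single study outcome of `db`,
# bypassing the balance gate (used by recovery experiments)
ps_stratified_estimate <- function(db, seed = 1) {
  coh <- select_new_users(db, db$truth$config$target_code,
                          db$truth$config$comparator_code)
  cov <- add_baseline_covariates(
    coh, db,
    exclude_codes = c(db$truth$outcome_codes,
                      db$truth$negative_control_codes, "ra")
  )
  cov_cols <- c("age_at_index", "female",
                setdiff(names(cov), names(coh)))
  ps <- fit_propensity_model(cov[cov_cols], cov$arm, seed = seed)
  strata <- stratify_by_quintile(ps$scores)
  eras <- build_drug_eras(db$drug_exposures)
  ev <- dplyr::filter(db$condition_occurrences,
                      condition_code == db$truth$outcome_codes[1])
  ri <- compute_time_at_risk(coh, eras, ev, tar_spec("intention_to_treat"),
                             db$observation_periods)
  st <- stats::setNames(strata, coh$person_id)
  fit_stratified_cox(ri, st[as.character(ri$person_id)])
}

# plain two-arm exponential survival data as a ready-made risk-interval
# table (independent of the claims generator)
simple_risk_intervals <- function(n = 2000, hr = 1, lambda = 2e-3,
                                  horizon = 30) {
  arm <- rep(c("target", "comparator"), length.out = n)
  rate <- lambda * ifelse(arm == "target", hr, 1)
  t <- ceiling(rexp(n, rate))
  event <- t <= horizon
  end <- pmin(t, horizon)
  tibble::tibble(
    person_id = seq_len(n),
    arm = arm,
    start_day = 1L,
    end_day = as.integer(end),
    event = event,
    event_day = ifelse(event, as.integer(end), NA_integer_),
    person_days = as.integer(end)
  )
}
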