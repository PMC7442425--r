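#' Simulation configuration for the synthetic claims generator
#'
#' Bundles every knob of the synthetic longitudinal claims database:
#' population size, baseline covariates, the logistic treatment-assignment
#' model (the confounding channel that propensity-score stratification must
#' remove), exponential outcome hazards with known true hazard ratios,
#' negative-control outcomes (true HR fixed at 1) with optional injectable
#' systematic bias through an unmeasured confounder, exposure refill
#' structure, and the observation window around the index day.
#'
#' Defaults emulate a rheumatoid-arthritis new-user population: mostly
#' female, with lupus and psoriasis history pushing treatment choice in
#' opposite directions, 30-day drug supplies refilled with short gaps, and
#' several years of enrolment around therapy initiation. Time is integer
#' days; day 0 is each person's observation start (anchored at 2010-01-01
#' for age and season arithmetic).
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; the population, treatment and outcome stages
#'   draw from separate streams derived from it, so adding outcomes does not
#'   perturb the population.
#' @param covariates Data frame with columns `name` and `prevalence` (binary
#'   baseline covariates, recorded as condition occurrences on or before the
#'   index day). Must include `female`.
#' @param treatment_intercept,treatment_coefs Logistic model of target (vs
#'   comparator) initiation: log-odds = intercept + sum(coefs * covariates) +
#'   `unmeasured_treat_coef` * U.
#' @param outcomes Named list of study outcomes; each element a list with
#'   `baseline_hazard` (events per person-day), `log_hr` (true log hazard
#'   ratio of target vs comparator) and optional named `covariate_effects`
#'   (log-hazard per covariate).
#' @param n_negative_controls Number of negative-control outcome codes
#'   (`nc_01`, `nc_02`, ...); their true exposure log-HR is always 0.
#' @param nc_baseline_hazard Baseline daily hazard shared by the negative
#'   controls.
#' @param bias Scalar or length-`n_negative_controls` vector: log-hazard
#'   effect of the unmeasured confounder U on each negative control. With
#'   `unmeasured_treat_coef != 0` this injects systematic error that
#'   empirical calibration should recover.
#' @param unmeasured_prevalence,unmeasured_treat_coef Prevalence of the
#'   latent confounder U and its log-odds effect on treatment choice. U is
#'   never written to the output tables.
#' @param exposure List: `days_supplied`, and inclusive integer ranges
#'   `n_refills` and `refill_gap` (unexposed days between consecutive
#'   dispensings); equal range endpoints give a deterministic schedule.
#' @param observation List of inclusive integer ranges `days_before_index`
#'   and `days_after_index`.
#' @param indication_code,indication_prevalence Condition code marking the
#'   treatment indication (recorded on or before index) and the fraction of
#'   persons carrying it.
#' @param age_range Inclusive age range (years) at day 0.
#' @param target_code,comparator_code Drug codes written to
#'   `drug_exposures`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_persons = 500, seed = 1)
#' db <- simulate_claims(cfg)
#' db
sim_config <- function(n_persons = 5000,
                       seed = 42,
                       covariates = default_covariates(),
                       treatment_intercept = 0.3,
                       treatment_coefs = c(
                         female = 0.45, sle = 1.0, psoriasis = -1.2,
                         crohns_disease = -1.1, heart_disease = -0.4,
                         diabetes = 0.2
                       ),
                       outcomes = list(
                         cv_event = list(
                           baseline_hazard = 1e-3,
                           log_hr = 0,
                           covariate_effects = c(
                             sle = 0.7, heart_disease = 0.9,
                             female = -0.3, diabetes = 0.4
                           )
                         )
                       ),
                       n_negative_controls = 40,
                       nc_baseline_hazard = 2e-4,
                       bias = 0,
                       unmeasured_prevalence = 0.3,
                       unmeasured_treat_coef = 0,
                       exposure = list(
                         days_supplied = 30,
                         n_refills = c(1L, 6L),
                         refill_gap = c(0L, 20L)
                       ),
                       observation = list(
                         days_before_index = c(200L, 1825L),
                         days_after_index = c(90L, 1460L)
                       ),
                       indication_code = "ra",
                       indication_prevalence = 0.97,
                       age_range = c(16L, 90L),
                       target_code = "target_drug",
                       comparator_code = "comparator_drug") {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' Default baseline covariate specification
#'
#' Prevalences loosely follow the baseline characteristics of commercially
#' insured rheumatoid-arthritis patients (predominantly female, frequent
#' hyperlipidaemia, rare Crohn's disease).
#'
#' @return Tibble with columns `name`, `prevalence`.
#' @export
default_covariates <- function() {
  tibble::tribble(
    ~name,             ~prevalence,
    "female",          0.78,
    "sle",             0.08,
    "psoriasis",       0.06,
    "crohns_disease",  0.012,
    "heart_disease",   0.155,
    "diabetes",        0.14,
    "hyperlipidemia",  0.31,
    "renal_impairment", 0.03
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1 ||
      cfg$n_persons < 1) {
    abort("`n_persons` must be a single positive count.",
          class = "safetysignal_config_error")
  }
  cov <- cfg$covariates
  if (!all(c("name", "prevalence") %in% names(cov))) {
    abort("`covariates` needs columns `name` and `prevalence`.",
          class = "safetysignal_config_error")
  }
  if (any(cov$prevalence < 0 | cov$prevalence > 1)) {
    abort("covariate prevalences must lie in [0, 1].",
          class = "safetysignal_config_error")
  }
  unknown <- setdiff(names(cfg$treatment_coefs), cov$name)
  if (length(unknown)) {
    abort(paste0("treatment coefficients reference unknown covariates: ",
                 paste(unknown, collapse = ", ")),
          class = "safetysignal_config_error")
  }
  for (nm in names(cfg$outcomes)) {
    om <- cfg$outcomes[[nm]]
    if (!is.numeric(om$baseline_hazard) || om$baseline_hazard <= 0) {
      abort(paste0("baseline hazard for outcome `", nm,
                   "` must be positive."),
            class = "safetysignal_config_error")
    }
    bad <- setdiff(names(om$covariate_effects), cov$name)
    if (length(bad)) {
      abort(paste0("outcome `", nm, "` references unknown covariates: ",
                   paste(bad, collapse = ", ")),
            class = "safetysignal_config_error")
    }
  }
  if (cfg$nc_baseline_hazard <= 0) {
    abort("`nc_baseline_hazard` must be positive.",
          class = "safetysignal_config_error")
  }
  nb <- length(cfg$bias)
  if (!nb %in% c(1L, cfg$n_negative_controls)) {
    abort("`bias` must be scalar or one value per negative control.",
          class = "safetysignal_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  persons:", x$n_persons, " seed:", x$seed, "\n")
  cat("  covariates:", paste(x$covariates$name, collapse = ", "), "\n")
  cat("  outcomes:", paste(names(x$outcomes), collapse = ", "),
      " (+", x$n_negative_controls, "negative controls)\n")
  invisible(x)
}
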