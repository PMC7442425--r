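#' Generate the simulated population
#'
#' Draws persons, their single observation period, their baseline binary
#' covariates (written as condition occurrences on or before the index day),
#' the treatment-indication code, and the latent unmeasured confounder U.
#' The index day (therapy initiation anchor used by later stages) is drawn
#' here so that the observation window can be placed around it.
#'
#' @param config A [sim_config()].
#' @return A `claims_db`: list with tibbles `persons`, `observation_periods`,
#'   `drug_exposures` (empty at this stage), `condition_occurrences`, and a
#'   `truth` element holding the config, the realized covariate matrix
#'   (including U) and per-person index days.
#' @export
generate_population <- function(config) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, 1L))
  n <- as.integer(config$n_persons)

  age0 <- sample(config$age_range[1]:config$age_range[2], n, replace = TRUE)
  covs <- purrr::map_dfc(
    stats::setNames(seq_len(nrow(config$covariates)), config$covariates$name),
    function(i) rbinom(n, 1L, config$covariates$prevalence[i])
  )
  u <- rbinom(n, 1L, config$unmeasured_prevalence)

  before <- sample_range(config$observation$days_before_index, n)
  after <- sample_range(config$observation$days_after_index, n)
  index_day <- before
  obs_end <- before + after

  persons <- tibble::tibble(
    person_id = seq_len(n),
    year_of_birth = 2010L - age0,
    sex = ifelse(covs$female == 1L, "female", "male")
  )
  observation_periods <- tibble::tibble(
    person_id = seq_len(n), start_day = 0L, end_day = obs_end
  )

  # baseline history: one row per positive covariate, on or before index
  cond <- tidyr::pivot_longer(
    dplyr::bind_cols(person_id = seq_len(n), index_day = index_day, covs),
    cols = -c("person_id", "index_day"),
    names_to = "condition_code", values_to = "present"
  )
  # sex lives in the persons table, not in the condition stream
  cond <- dplyr::filter(cond, .data$present == 1L,
                        .data$condition_code != "female")
  cond$day <- as.integer(floor(runif(nrow(cond)) * (cond$index_day + 1L)))
  has_ind <- rbinom(n, 1L, config$indication_prevalence) == 1L
  ind <- tibble::tibble(
    person_id = which(has_ind),
    condition_code = config$indication_code,
    day = as.integer(floor(runif(sum(has_ind)) * (index_day[has_ind] + 1L)))
  )
  condition_occurrences <- dplyr::arrange(
    dplyr::bind_rows(
      dplyr::select(cond, "person_id", "condition_code", "day"), ind
    ),
    .data$person_id, .data$day
  )

  new_claims_db(
    persons = persons,
    observation_periods = observation_periods,
    drug_exposures = tibble::tibble(
      person_id = integer(), drug_code = character(),
      start_day = integer(), days_supplied = integer()
    ),
    condition_occurrences = condition_occurrences,
    truth = list(
      config = config,
      covariates = dplyr::bind_cols(person_id = seq_len(n), covs, u = u),
      index_day = index_day
    )
  )
}

#' Assign study drugs and write era-fragmented exposure records
#'
#' Each person initiates exactly one study drug at their index day, chosen
#' by the logistic treatment model of the config (plus the unmeasured
#' confounder channel when enabled). Refill records follow the exposure
#' spec: each dispensing supplies `days_supplied` days and the next one
#' starts after a drawn unexposed gap, producing the fragmented exposure
#' stream that drug-era construction must stitch back together.
#'
#' @param db A `claims_db` from [generate_population()].
#' @param config Optional [sim_config()]; defaults to the one stored in
#'   `db$truth`.
#' @return The `claims_db` with populated `drug_exposures` and per-person
#'   arms recorded in `truth`.
#' @export
assign_treatments <- function(db, config = db$truth$config) {
  stopifnot(inherits(db, "claims_db"))
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, 2L))
  covs <- db$truth$covariates
  n <- nrow(covs)

  lp <- rep(config$treatment_intercept, n)
  for (nm in names(config$treatment_coefs)) {
    lp <- lp + config$treatment_coefs[[nm]] * covs[[nm]]
  }
  lp <- lp + config$unmeasured_treat_coef * covs$u
  target <- rbinom(n, 1L, plogis(lp)) == 1L
  drug <- ifelse(target, config$target_code, config$comparator_code)

  supply <- as.integer(config$exposure$days_supplied)
  n_refills <- sample_range(config$exposure$n_refills, n)
  index_day <- db$truth$index_day
  obs_end <- db$observation_periods$end_day

  k <- n_refills + 1L
  pid <- rep(seq_len(n), k)
  rec <- sequence(k)
  gap <- sample_range(config$exposure$refill_gap, length(pid))
  inc <- ifelse(rec == 1L, 0L, gap + supply)
  exposures <- tibble::tibble(person_id = pid, rec = rec, inc = inc) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(start_day = index_day[.data$person_id[1]] +
                    cumsum(.data$inc)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      drug_code = drug[.data$person_id],
      obs_end = obs_end[.data$person_id]
    ) |>
    dplyr::filter(.data$start_day <= .data$obs_end) |>
    dplyr::mutate(
      start_day = as.integer(.data$start_day),
      days_supplied = pmin(supply, .data$obs_end - .data$start_day + 1L)
    ) |>
    dplyr::select("person_id", "drug_code", "start_day", "days_supplied")
  db$drug_exposures <- exposures
  db$truth$arm <- ifelse(target, "target", "comparator")
  db
}

#' Generate study and negative-control outcome occurrences
#'
#' Event times are drawn from exponential hazards
#' `lambda * exp(covariate effects + arm effect (+ bias * U))`, measured
#' from the index day; the first event per outcome per person is recorded
#' at `index + ceiling(t)` when it falls inside the observation period
#' (later events are censored by period end and never written). Negative
#' controls have arm effect exactly 0; their only non-null channel is the
#' configured unmeasured-confounder bias.
#'
#' @inheritParams assign_treatments
#' @param multi_event If `TRUE`, subsequent events are drawn from the same
#'   hazard after each event (recurrent-event stream for self-controlled
#'   designs); default records first events only.
#' @return The `claims_db` with outcome rows appended to
#'   `condition_occurrences` and realized true log-HRs stored in `truth`.
#' @export
generate_outcomes <- function(db, config = db$truth$config,
                              multi_event = FALSE) {
  stopifnot(inherits(db, "claims_db"))
  if (is.null(db$truth$arm)) {
    abort("treatments must be assigned before outcomes are generated.")
  }
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$seed, 3L))
  covs <- db$truth$covariates
  n <- nrow(covs)
  is_target <- db$truth$arm == "target"
  index_day <- db$truth$index_day
  obs_end <- db$observation_periods$end_day

  nc_codes <- sprintf("nc_%02d", seq_len(config$n_negative_controls))
  bias <- rep(config$bias, length.out = config$n_negative_controls)
  specs <- c(
    config$outcomes,
    stats::setNames(purrr::map(seq_along(nc_codes), function(k) {
      list(baseline_hazard = config$nc_baseline_hazard, log_hr = 0,
           covariate_effects = NULL, u_effect = bias[k])
    }), nc_codes)
  )

  out_rows <- purrr::imap(specs, function(om, code) {
    lh <- log(om$baseline_hazard) + om$log_hr * is_target
    for (nm in names(om$covariate_effects)) {
      lh <- lh + om$covariate_effects[[nm]] * covs[[nm]]
    }
    if (!is.null(om$u_effect)) lh <- lh + om$u_effect * covs$u
    rate <- exp(lh)
    horizon <- obs_end - index_day
    if (!multi_event) {
      day <- index_day + ceiling(rexp(n, rate))
      keep <- day <= obs_end
      tibble::tibble(person_id = which(keep), condition_code = code,
                     day = as.integer(day[keep]))
    } else {
      purrr::map_dfr(which(horizon >= 1L), function(i) {
        t <- 0
        days <- integer()
        repeat {
          t <- t + rexp(1L, rate[i])
          if (ceiling(t) > horizon[i]) break
          days <- c(days, as.integer(index_day[i] + ceiling(t)))
        }
        if (!length(days)) return(NULL)
        tibble::tibble(person_id = i, condition_code = code, day = days)
      })
    }
  })
  db$condition_occurrences <- dplyr::arrange(
    dplyr::bind_rows(db$condition_occurrences,
                     purrr::list_rbind(unname(out_rows))),
    .data$person_id, .data$day
  )
  db$truth$outcome_codes <- names(config$outcomes)
  db$truth$negative_control_codes <- nc_codes
  db$truth$true_log_hr <- c(
    purrr::map_dbl(config$outcomes, "log_hr"),
    stats::setNames(rep(0, length(nc_codes)), nc_codes)
  )
  db
}

#' Simulate a complete claims database
#'
#' Convenience wrapper running [generate_population()],
#' [assign_treatments()] and [generate_outcomes()] in order.
#'
#' @inheritParams generate_population
#' @inheritParams generate_outcomes
#' @return A fully populated `claims_db`.
#' @export
simulate_claims <- function(config, multi_event = FALSE) {
  config |>
    generate_population() |>
    assign_treatments() |>
    generate_outcomes(multi_event = multi_event)
}

#' Simulate recurrent-event data for the self-controlled case series
#'
#' Generates per-person observation windows, a single exposure era placed
#' inside each window, and events from a piecewise-constant Poisson process
#' whose rate is `baseline_rate * frailty * irr^exposed`. The per-person
#' multiplicative frailty creates the between-person heterogeneity that the
#' within-person design is immune to.
#'
#' @param n_persons Number of persons.
#' @param obs_days Observation length in days (all persons identical).
#' @param exposure_start,exposure_length Inclusive integer ranges for era
#'   placement.
#' @param baseline_rate Events per unexposed person-day.
#' @param irr True incidence rate ratio during exposure.
#' @param frailty_sd SD of the per-person log-normal frailty (0 = none).
#' @param seed Integer seed.
#' @return List of tibbles `observation_periods`, `eras`
#'   (person_id/era_start_day/era_end_day) and `events` (person_id/day).
#' @export
simulate_sccs_data <- function(n_persons = 500, obs_days = 730,
                               exposure_start = c(100L, 400L),
                               exposure_length = c(90L, 270L),
                               baseline_rate = 6e-4, irr = 1,
                               frailty_sd = 0, seed = 1) {
  set.seed(stream_seed(seed, 4L))
  start <- sample_range(exposure_start, n_persons)
  len <- sample_range(exposure_length, n_persons)
  end <- pmin(start + len - 1L, obs_days - 1L)
  frail <- exp(rnorm(n_persons, 0, frailty_sd))

  events <- purrr::map_dfr(seq_len(n_persons), function(i) {
    segs <- tibble::tibble(
      s = c(0L, start[i], end[i] + 1L),
      e = c(start[i] - 1L, end[i], obs_days - 1L),
      rate = baseline_rate * frail[i] * c(1, irr, 1)
    )
    segs <- segs[segs$e >= segs$s, ]
    days <- purrr::pmap(segs, function(s, e, rate) {
      k <- rpois(1L, rate * (e - s + 1L))
      if (k == 0L) return(integer())
      sort(sample(s:e, k, replace = TRUE))
    })
    days <- unlist(days)
    if (!length(days)) return(NULL)
    tibble::tibble(person_id = i, day = as.integer(days))
  })

  list(
    observation_periods = tibble::tibble(
      person_id = seq_len(n_persons), start_day = 0L,
      end_day = obs_days - 1L
    ),
    eras = tibble::tibble(
      person_id = seq_len(n_persons),
      era_start_day = start, era_end_day = end
    ),
    events = events
  )
}

new_claims_db <- function(persons, observation_periods, drug_exposures,
                          condition_occurrences, truth) {
  structure(
    list(persons = persons, observation_periods = observation_periods,
         drug_exposures = drug_exposures,
         condition_occurrences = condition_occurrences, truth = truth),
    class = "claims_db"
  )
}

#' @export
print.claims_db <- function(x, ...) {
  cat("<claims_db>\n")
  cat("  persons:", nrow(x$persons),
      " drug exposures:", nrow(x$drug_exposures),
      " condition occurrences:", nrow(x$condition_occurrences), "\n")
  if (!is.null(x$truth$arm)) {
    cat("  arms:", sum(x$truth$arm == "target"), "target /",
        sum(x$truth$arm == "comparator"), "comparator\n")
  }
  invisible(x)
}

# independent integer streams per generation stage, kept under 2^31
stream_seed <- function(seed, stage) {
  (as.integer(seed) * 7L + stage * 1000003L) %% .Machine$integer.max
}

sample_range <- function(rng, n) {
  if (n == 0L) return(integer())
  rng <- as.integer(rng)
  if (length(rng) == 1L) rng <- c(rng, rng)
  if (rng[1] == rng[2]) return(rep(rng[1], n))
  as.integer(sample(rng[1]:rng[2], n, replace = TRUE))
}
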