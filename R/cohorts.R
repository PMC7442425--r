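#' Select new users for the active-comparator cohort
#'
#' Builds the two-arm new-user cohort: each person's index is the start of
#' their first era of whichever study drug they initiated first. Persons
#' initiating both drugs on the same day are excluded, as are persons
#' younger than `min_age` at index, persons without the indication code on
#' or before index, and persons with fewer than `washout_days` of
#' continuous observation before index. Each person contributes to exactly
#' one arm.
#'
#' @param db A `claims_db`, or a plain list with tibbles `persons`,
#'   `observation_periods`, `drug_exposures`, `condition_occurrences`.
#' @param target_code,comparator_code Study drug codes (must differ).
#' @param indication_code Condition code required on or before index.
#' @param washout_days Minimum observed days before index (default 365).
#' @param min_age Minimum age in years at index (default 18).
#' @param max_gap_days Gap rule for the underlying drug eras.
#' @param ref_year Calendar year of day 0 (age arithmetic).
#' @return Tibble of cohort entries: `person_id`, `arm`
#'   (`"target"`/`"comparator"`), `drug_code`, `index_day`, `age_at_index`,
#'   `female`. An `attrition` attribute counts exclusions by reason.
#' @export
select_new_users <- function(db, target_code, comparator_code,
                             indication_code = "ra", washout_days = 365,
                             min_age = 18, max_gap_days = 90,
                             ref_year = 2010) {
  if (identical(target_code, comparator_code)) {
    abort("`target_code` and `comparator_code` must differ.",
          class = "safetysignal_config_error")
  }
  eras <- build_drug_eras(
    dplyr::filter(db$drug_exposures,
                  .data$drug_code %in% c(target_code, comparator_code)),
    max_gap_days = max_gap_days
  )
  # eras arrive sorted by person, drug, start: the first row per
  # person+drug is that drug's first era; the earliest of those per person
  # is the candidate index
  fe <- eras[!duplicated(eras[c("person_id", "drug_code")]), ]
  fe <- fe[order(fe$person_id, fe$era_start_day, fe$drug_code), ]
  lead_id <- c(fe$person_id[-1], NA)
  lead_start <- c(fe$era_start_day[-1], NA)
  first_row <- !duplicated(fe$person_id)
  firsts <- tibble::tibble(
    person_id = fe$person_id[first_row],
    drug_code = fe$drug_code[first_row],
    index_day = fe$era_start_day[first_row],
    tie = !is.na(lead_id[first_row]) &
      lead_id[first_row] == fe$person_id[first_row] &
      lead_start[first_row] == fe$era_start_day[first_row]
  )
  attr_counts <- c(candidates = nrow(firsts))

  cand <- dplyr::filter(firsts, !.data$tie)
  attr_counts["same_day_initiation"] <- nrow(firsts) - nrow(cand)

  cand <- cand |>
    dplyr::inner_join(db$persons, by = "person_id") |>
    dplyr::inner_join(db$observation_periods, by = "person_id") |>
    dplyr::mutate(
      age_at_index = (ref_year - .data$year_of_birth) +
        .data$index_day %/% 365L,
      female = as.integer(.data$sex == "female")
    )

  ok_age <- cand$age_at_index >= min_age
  attr_counts["under_min_age"] <- sum(!ok_age)
  cand <- cand[ok_age, ]

  ind <- db$condition_occurrences |>
    dplyr::filter(.data$condition_code == indication_code) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_ind = min(.data$day), .groups = "drop")
  cand <- dplyr::left_join(cand, ind, by = "person_id")
  ok_ind <- !is.na(cand$first_ind) & cand$first_ind <= cand$index_day
  attr_counts["no_prior_indication"] <- sum(!ok_ind)
  cand <- cand[ok_ind, ]

  ok_wash <- cand$index_day - cand$start_day >= washout_days
  attr_counts["insufficient_washout"] <- sum(!ok_wash)
  cand <- cand[ok_wash, ]

  out <- cand |>
    dplyr::mutate(arm = factor(
      ifelse(.data$drug_code == target_code, "target", "comparator"),
      levels = c("comparator", "target")
    )) |>
    dplyr::select("person_id", "arm", "drug_code", "index_day",
                  "age_at_index", "female")
  attr(out, "attrition") <- attr_counts
  out
}

#' Attach baseline covariates to a cohort
#'
#' Adds one binary indicator per condition code observed on or before each
#' person's index day (the "all binary indicators present in the table"
#' large-scale covariate construction), plus `age_at_index` and `female`
#' carried from the cohort.
#'
#' @param cohort Output of [select_new_users()].
#' @param db The `claims_db` (or list of tables) the cohort was built from.
#' @param exclude_codes Codes never used as covariates (e.g. outcome and
#'   negative-control codes, which must not enter the propensity model).
#' @return The cohort tibble with one 0/1 column per retained code.
#' @export
add_baseline_covariates <- function(cohort, db, exclude_codes = character()) {
  hist <- db$condition_occurrences |>
    dplyr::filter(!.data$condition_code %in% exclude_codes) |>
    dplyr::inner_join(dplyr::select(cohort, "person_id", "index_day"),
                      by = "person_id") |>
    dplyr::filter(.data$day <= .data$index_day) |>
    dplyr::distinct(.data$person_id, .data$condition_code) |>
    dplyr::mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "condition_code",
                       values_from = "present", values_fill = 0L)
  out <- dplyr::left_join(cohort, hist, by = "person_id")
  new_cols <- setdiff(names(out), names(cohort))
  out[new_cols] <- lapply(out[new_cols], function(x) tidyr::replace_na(x, 0L))
  out
}

#' Time-at-risk specification
#'
#' Defines how follow-up windows are carved out of observation time:
#' intention-to-treat fixes the window at `fixed_end_offset_days` after
#' index (30 days mirrors a short treatment course), on-treatment follows
#' the person's drug era plus a `post_exposure_washout_days` washout (14
#' days). Follow-up always starts `start_offset_days` (default 1) after
#' index, so index-day events never count.
#'
#' @param mode `"intention_to_treat"` or `"on_treatment"`.
#' @param start_offset_days First day of follow-up relative to index.
#' @param fixed_end_offset_days Window end relative to index (ITT mode).
#' @param post_exposure_washout_days Days added after era end (on-treatment
#'   mode).
#' @param era_gap_days Gap rule used when the driving eras are rebuilt.
#' @return An object of class `tar_spec`.
#' @export
tar_spec <- function(mode = c("intention_to_treat", "on_treatment"),
                     start_offset_days = 1,
                     fixed_end_offset_days = 30,
                     post_exposure_washout_days = 14,
                     era_gap_days = 90) {
  mode <- match.arg(mode)
  stopifnot(start_offset_days >= 0)
  structure(
    list(mode = mode, start_offset_days = as.integer(start_offset_days),
         fixed_end_offset_days = as.integer(fixed_end_offset_days),
         post_exposure_washout_days =
           as.integer(post_exposure_washout_days),
         era_gap_days = as.integer(era_gap_days)),
    class = "tar_spec"
  )
}

#' Compute per-person risk intervals
#'
#' Realizes a [tar_spec()] for every cohort entry. Follow-up runs from
#' `index + start_offset` to the first of: first qualifying outcome event,
#' end of observation, and either the fixed window end (intention-to-treat)
#' or the person's index drug era end plus washout (on-treatment). Entries
#' whose interval would end before it starts are dropped and counted in the
#' `dropped` attribute.
#'
#' @param cohort Output of [select_new_users()].
#' @param eras Drug eras (from [build_drug_eras()]) covering the cohort's
#'   drugs; only needed in on-treatment mode.
#' @param events Data frame of outcome occurrences with `person_id`, `day`
#'   (already filtered to one outcome code).
#' @param spec A [tar_spec()].
#' @param observation_periods Table with `person_id`, `start_day`,
#'   `end_day`.
#' @return Tibble of risk intervals: `person_id`, `arm`, `start_day`,
#'   `end_day`, `event`, `event_day`, `person_days`.
#' @export
compute_time_at_risk <- function(cohort, eras = NULL, events, spec,
                                 observation_periods) {
  stopifnot(inherits(spec, "tar_spec"))
  x <- cohort |>
    dplyr::inner_join(
      dplyr::select(observation_periods, "person_id", obs_end = "end_day"),
      by = "person_id"
    ) |>
    dplyr::mutate(start_day = .data$index_day + spec$start_offset_days)

  first_ev <- events |>
    dplyr::inner_join(dplyr::select(x, "person_id", "start_day"),
                      by = "person_id") |>
    dplyr::filter(.data$day >= .data$start_day) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_event = min(.data$day, Inf), .groups = "drop")
  x <- dplyr::left_join(x, first_ev, by = "person_id")

  if (spec$mode == "intention_to_treat") {
    x$tar_end <- x$index_day + spec$fixed_end_offset_days
  } else {
    if (is.null(eras)) {
      abort("on-treatment mode needs the drug eras.",
            class = "safetysignal_config_error")
    }
    idx_era <- x |>
      dplyr::select("person_id", "drug_code", "index_day") |>
      dplyr::inner_join(eras, by = c("person_id", "drug_code")) |>
      dplyr::filter(.data$era_start_day <= .data$index_day,
                    .data$era_end_day >= .data$index_day) |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(era_end = max(.data$era_end_day), .groups = "drop")
    x <- dplyr::left_join(x, idx_era, by = "person_id")
    x$tar_end <- x$era_end + spec$post_exposure_washout_days
  }

  x <- x |>
    dplyr::mutate(
      end_day = pmin(.data$tar_end, .data$obs_end,
                     dplyr::coalesce(.data$first_event, Inf)),
      end_day = as.integer(.data$end_day),
      event = !is.na(.data$first_event) &
        is.finite(.data$first_event) &
        .data$first_event <= .data$end_day,
      event_day = dplyr::if_else(.data$event,
                                 as.integer(.data$first_event),
                                 NA_integer_)
    )
  dropped <- x$end_day < x$start_day | is.na(x$end_day)
  out <- x |>
    dplyr::filter(!dropped) |>
    dplyr::mutate(person_days = .data$end_day - .data$start_day + 1L) |>
    dplyr::select("person_id", "arm", "start_day", "end_day", "event",
                  "event_day", "person_days")
  attr(out, "dropped") <- sum(dropped)
  out
}
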