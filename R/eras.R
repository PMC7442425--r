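#' Build drug eras by gap stitching
#'
#' Reconstructs periods of persistent exposure from dispensing records:
#' consecutive records of the same person and drug are merged into one era
#' when the number of unexposed days between them
#' (`next_start_day - previous_era_end_day - 1`) is at most `max_gap_days`.
#' A record covers days `[start_day, start_day + days_supplied - 1]`
#' inclusive; era ends take overlapping records into account via a running
#' maximum.
#'
#' @param exposures Data frame with columns `person_id`, `drug_code`,
#'   `start_day`, `days_supplied` (all `days_supplied >= 1`).
#' @param max_gap_days Maximum tolerated unexposed gap; 90 days is the
#'   conventional persistence rule for chronic therapy.
#' @return Tibble with `person_id`, `drug_code`, `era_start_day`,
#'   `era_end_day` (inclusive), `n_records`, one row per era.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   person_id = 1L, drug_code = "a",
#'   start_day = c(0L, 100L), days_supplied = c(30L, 30L)
#' )
#' build_drug_eras(recs) # one era [0, 129]: 70 unexposed days <= 90
build_drug_eras <- function(exposures, max_gap_days = 90) {
  req <- c("person_id", "drug_code", "start_day", "days_supplied")
  stopifnot(all(req %in% names(exposures)))
  bad <- which(exposures$days_supplied < 1)
  if (length(bad)) {
    abort(paste0("`days_supplied` must be >= 1; offending row(s): ",
                 paste(head(bad, 5L), collapse = ", ")),
          class = "safetysignal_data_error")
  }
  d <- data.table::as.data.table(exposures[req])
  d[, end := start_day + days_supplied - 1L]
  data.table::setorder(d, person_id, drug_code, start_day, end)
  d[, run_end := data.table::shift(cummax(end)),
    by = c("person_id", "drug_code")]
  d[, era := cumsum(is.na(run_end) |
                      start_day - run_end - 1L > max_gap_days)]
  res <- d[, list(person_id = person_id[1], drug_code = drug_code[1],
                  era_start_day = min(start_day),
                  era_end_day = max(end), n_records = .N),
           by = era]
  out <- tibble::as_tibble(res)
  out$era <- NULL
  dplyr::arrange(out, .data$person_id, .data$drug_code,
                 .data$era_start_day)
}

#' Derive a combination-therapy exposure code
#'
#' Expresses a "drug A plus drug B" cohort as a synthetic exposure code:
#' for each person, if the first era of the second-started drug begins
#' within `window` days of the first era of the other drug and the earlier
#' era is still ongoing at that point (the two drugs overlap at the
#' combination index), all dispensing records of either drug starting on or
#' after that day are re-labelled `combo_code`. The combination index is
#' the second drug's start, so a new-user cohort built on `combo_code`
#' indexes at combination initiation.
#'
#' @param exposures Dispensing records (see [build_drug_eras()]).
#' @param drug_a,drug_b The two component codes.
#' @param combo_code Code assigned to the derived records.
#' @param window Inclusive day range (default 0--30) within which the second
#'   drug must start after the first.
#' @param max_gap_days Gap rule used to form the component eras.
#' @return Tibble of derived exposure records in the input schema.
#' @export
derive_combination_exposure <- function(exposures, drug_a, drug_b,
                                        combo_code = paste(drug_a, drug_b,
                                                           sep = "+"),
                                        window = c(0L, 30L),
                                        max_gap_days = 90) {
  eras <- build_drug_eras(
    dplyr::filter(exposures, .data$drug_code %in% c(drug_a, drug_b)),
    max_gap_days = max_gap_days
  )
  firsts <- eras |>
    dplyr::group_by(.data$person_id, .data$drug_code) |>
    dplyr::slice_min(.data$era_start_day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  wide <- firsts |>
    dplyr::filter(.data$drug_code %in% c(drug_a, drug_b)) |>
    tidyr::pivot_wider(id_cols = "person_id",
                       names_from = "drug_code",
                       values_from = c("era_start_day", "era_end_day"))
  sa <- wide[[paste0("era_start_day_", drug_a)]]
  sb <- wide[[paste0("era_start_day_", drug_b)]]
  ea <- wide[[paste0("era_end_day_", drug_a)]]
  eb <- wide[[paste0("era_end_day_", drug_b)]]
  if (is.null(sa) || is.null(sb)) {
    return(exposures[0, ])
  }
  first_start <- pmin(sa, sb)
  second_start <- pmax(sa, sb)
  first_end <- ifelse(sa <= sb, ea, eb)
  ok <- !is.na(sa) & !is.na(sb) &
    (second_start - first_start) >= window[1] &
    (second_start - first_start) <= window[2] &
    first_end >= second_start
  idx <- tibble::tibble(person_id = wide$person_id[ok],
                        combo_index = second_start[ok])
  exposures |>
    dplyr::filter(.data$drug_code %in% c(drug_a, drug_b)) |>
    dplyr::inner_join(idx, by = "person_id") |>
    dplyr::filter(.data$start_day >= .data$combo_index) |>
    dplyr::mutate(drug_code = combo_code) |>
    dplyr::select("person_id", "drug_code", "start_day", "days_supplied")
}
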