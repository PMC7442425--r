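#' Published per-database counts and incidence rates
#'
#' Aggregate patient counts, event counts and incidence rates (per 1000
#' person-years) of severe adverse events, per contributing database, as
#' published by a multinational network study of hydroxychloroquine (HCQ)
#' vs sulfasalazine (SSZ) new users and of HCQ plus azithromycin vs HCQ
#' plus amoxicillin, under 30-day intention-to-treat and on-treatment
#' follow-up. Event cells below the small-cell threshold appear exactly as
#' published, i.e. as the string `"<5"`, with the corresponding rate cell
#' a `"<"` bound. These rows are the worked input for
#' [pool_counts_and_rates()]: person-time is back-derived as
#' `events / rate` and the meta-analysis row is recomputed from it.
#'
#' @param comparison,outcome,tar Optional filters (`"hcq_ssz"` /
#'   `"hcq_azm_amx"`; `"cv_mortality"`, `"all_cause_mortality"`,
#'   `"heart_failure"`; `"30d"` / `"on_treatment"`).
#' @return Tibble with columns `comparison`, `outcome`, `tar`, `database`,
#'   `users_t`, `users_c`, `events_t`, `events_c` (character; may be
#'   masked), `rate_t`, `rate_c` (character; may be bounds).
#' @export
published_counts <- function(comparison = NULL, outcome = NULL,
                             tar = NULL) {
  path <- system.file("extdata", "published_counts.csv",
                      package = "safetysignal", mustWork = TRUE)
  d <- readr::read_csv(path, col_types = "cccciicccc", progress = FALSE)
  if (!is.null(comparison)) {
    d <- dplyr::filter(d, .data$comparison %in% .env$comparison)
  }
  if (!is.null(outcome)) {
    d <- dplyr::filter(d, .data$outcome %in% .env$outcome)
  }
  if (!is.null(tar)) d <- dplyr::filter(d, .data$tar %in% .env$tar)
  d
}
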