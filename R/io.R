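#' Write a simulated claims database to disk
#'
#' One CSV per table (header row, UTF-8) plus a `truth.json` sidecar with
#' the generating configuration and realized ground-truth parameters, so a
#' written database round-trips with its provenance.
#'
#' @param db A `claims_db`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_claims_db <- function(db, dir) {
  stopifnot(inherits(db, "claims_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("persons", "observation_periods", "drug_exposures",
               "condition_occurrences")) {
    readr::write_csv(db[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  truth <- db$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a claims database from disk
#'
#' Reads the four-table CSV layout written by [write_claims_db()] (or any
#' real extract in the same minimal schema). The `truth.json` sidecar is
#' loaded when present.
#'
#' @param dir Directory containing the CSVs.
#' @return A `claims_db`.
#' @export
read_claims_db <- function(dir) {
  rd <- function(nm, types) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                    col_types = types, progress = FALSE)
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    list()
  }
  new_claims_db(
    persons = rd("persons", "iic"),
    observation_periods = rd("observation_periods", "iii"),
    drug_exposures = rd("drug_exposures", "icii"),
    condition_occurrences = rd("condition_occurrences", "ici"),
    truth = truth
  )
}
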