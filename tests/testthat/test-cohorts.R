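recs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(person_id = 1L, drug_code = "a",
                 start_day = as.integer(m[, 1]),
                 days_supplied = as.integer(m[, 2]))
}

test_that("era construction applies the 90-day gap rule on both sides of the boundary", {
  # 70 unexposed days between end (29) and next start (100): merge
  e <- build_drug_eras(recs(0, 30, 100, 30))
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$era_start_day, e$era_end_day), c(0L, 129L))

  # 91 unexposed days (30..120): split
  e <- build_drug_eras(recs(0, 30, 121, 30))
  expect_equal(nrow(e), 2L)
  expect_equal(e$era_start_day, c(0L, 121L))

  # exactly 90 unexposed days (30..119): still one era
  e <- build_drug_eras(recs(0, 30, 120, 30))
  expect_equal(nrow(e), 1L)
  expect_equal(e$era_end_day, 149L)

  # single record is its own era
  e <- build_drug_eras(recs(5, 10))
  expect_equal(c(e$era_start_day, e$era_end_day), c(5L, 14L))

  # overlapping dispensings: era end is the running maximum
  e <- build_drug_eras(recs(0, 60, 10, 10))
  expect_equal(c(e$era_start_day, e$era_end_day), c(0L, 59L))

  expect_error(build_drug_eras(recs(0, 0)),
               class = "safetysignal_data_error")
})

test_that("era construction is idempotent", {
  set.seed(42)
  x <- tibble::tibble(
    person_id = sample(1:20, 200, replace = TRUE),
    drug_code = sample(c("a", "b"), 200, replace = TRUE),
    start_day = sample(0:2000, 200, replace = TRUE),
    days_supplied = sample(1:90, 200, replace = TRUE)
  )
  e1 <- build_drug_eras(x)
  again <- e1 |>
    dplyr::transmute(person_id, drug_code, start_day = era_start_day,
                     days_supplied = era_end_day - era_start_day + 1L)
  e2 <- build_drug_eras(again)
  expect_equal(dplyr::select(e2, -n_records),
               dplyr::select(e1, -n_records))
})

make_db <- function() {
  # six hand-built persons exercising each eligibility rule
  persons <- tibble::tibble(
    person_id = 1:6,
    year_of_birth = c(1960L, 1994L, 1960L, 1960L, 1960L, 1955L),
    sex = c("female", "male", "female", "female", "male", "female")
  )
  observation_periods <- tibble::tibble(
    person_id = 1:6,
    start_day = c(0L, 0L, 0L, 100L, 0L, 0L),
    end_day = rep(2000L, 6)
  )
  drug_exposures <- tibble::tibble(
    person_id = c(1L, 2L, 3L, 4L, 5L, 5L, 6L),
    drug_code = c("t", "t", "c", "t", "t", "c", "c"),
    start_day = c(400L, 400L, 400L, 400L, 400L, 400L, 500L),
    days_supplied = rep(30L, 7)
  )
  condition_occurrences <- tibble::tibble(
    person_id = c(1L, 2L, 3L, 4L, 5L, 6L),
    condition_code = "ra",
    day = c(100L, 100L, 401L, 100L, 100L, 200L)
  )
  list(persons = persons, observation_periods = observation_periods,
       drug_exposures = drug_exposures,
       condition_occurrences = condition_occurrences)
}

test_that("new-user selection enforces age, indication, washout and same-day rules", {
  db <- make_db()
  coh <- select_new_users(db, "t", "c")
  # p1 eligible target; p6 eligible comparator
  expect_setequal(coh$person_id, c(1L, 6L))
  expect_equal(as.character(coh$arm[coh$person_id == 1L]), "target")
  expect_equal(as.character(coh$arm[coh$person_id == 6L]), "comparator")
  att <- attr(coh, "attrition")
  expect_equal(unname(att["under_min_age"]), 1)        # p2: age 17
  expect_equal(unname(att["no_prior_indication"]), 1)  # p3: RA day after
  expect_equal(unname(att["insufficient_washout"]), 1) # p4: 300 days
  expect_equal(unname(att["same_day_initiation"]), 1)  # p5
  expect_error(select_new_users(db, "t", "t"),
               class = "safetysignal_config_error")
})

test_that("time-at-risk intervals follow the first-of rule", {
  coh <- tibble::tibble(
    person_id = 1L, arm = factor("target", c("comparator", "target")),
    drug_code = "t", index_day = 400L, age_at_index = 50L, female = 1L
  )
  obs <- tibble::tibble(person_id = 1L, start_day = 0L, end_day = 2000L)
  itt <- tar_spec("intention_to_treat")

  # event on day index+15 ends the interval with event = TRUE
  ri <- compute_time_at_risk(coh, NULL,
                             tibble::tibble(person_id = 1L, day = 415L),
                             itt, obs)
  expect_equal(ri$end_day, 415L)
  expect_true(ri$event)
  expect_equal(ri$person_days, 15L)

  # no event: the 30-day window caps follow-up even with observation left
  ri <- compute_time_at_risk(coh, NULL,
                             tibble::tibble(person_id = integer(),
                                            day = integer()),
                             itt, obs)
  expect_equal(ri$end_day, 430L)
  expect_false(ri$event)
  expect_equal(ri$person_days, 30L)

  # index-day events do not count and the person stays in the cohort
  ri <- compute_time_at_risk(coh, NULL,
                             tibble::tibble(person_id = 1L, day = 400L),
                             itt, obs)
  expect_equal(nrow(ri), 1L)
  expect_false(ri$event)

  # on-treatment: era end + 14-day washout
  eras <- tibble::tibble(person_id = 1L, drug_code = "t",
                         era_start_day = 400L, era_end_day = 600L,
                         n_records = 3L)
  ot <- tar_spec("on_treatment")
  ri <- compute_time_at_risk(coh, eras,
                             tibble::tibble(person_id = integer(),
                                            day = integer()),
                             ot, obs)
  expect_equal(ri$end_day, 614L)

  # observation ending on the index day leaves no follow-up: dropped
  obs0 <- tibble::tibble(person_id = 1L, start_day = 0L, end_day = 400L)
  ri <- compute_time_at_risk(coh, NULL,
                             tibble::tibble(person_id = integer(),
                                            day = integer()),
                             itt, obs0)
  expect_equal(nrow(ri), 0L)
  expect_equal(attr(ri, "dropped"), 1L)
})

test_that("cohort entries satisfy their invariants on simulated databases", {
  for (s in 1:3) {
    db <- simulate_claims(null_config(n = 800, seed = 300 + s))
    coh <- select_new_users(db, "target_drug", "comparator_drug")
    expect_equal(anyDuplicated(coh$person_id), 0L)
    expect_true(all(coh$age_at_index >= 18))
    obs <- db$observation_periods
    expect_true(all(coh$index_day -
                      obs$start_day[match(coh$person_id,
                                          obs$person_id)] >= 365))
    ev <- dplyr::filter(db$condition_occurrences, condition_code == "y")
    ri <- compute_time_at_risk(coh, NULL, ev,
                               tar_spec("intention_to_treat"), obs)
    expect_true(all(ri$person_days >= 1 & ri$person_days <= 30))
    expect_lte(sum(ri$person_days), nrow(coh) * 30)
    expect_true(all(is.na(ri$event_day) |
                      (ri$event_day >= ri$start_day &
                         ri$event_day <= ri$end_day)))
  }
})

test_that("combination exposure indexes at the second drug's start", {
  ex <- tibble::tibble(
    person_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    drug_code = c("a", "b", "a", "b", "a", "b"),
    start_day = c(100L, 110L, 100L, 160L, 100L, 300L),
    days_supplied = c(30L, 30L, 30L, 30L, 30L, 30L)
  )
  combo <- derive_combination_exposure(ex, "a", "b", "ab")
  # p1: b starts 10 days after a while a ongoing -> combo from day 110
  expect_true(all(combo$drug_code == "ab"))
  expect_equal(min(combo$start_day[combo$person_id == 1L]), 110L)
  # p2: b starts 60 days later (outside 0-30 window) -> no combo rows
  expect_false(2L %in% combo$person_id)
  # p3: far outside the window
  expect_false(3L %in% combo$person_id)
})
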