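one_case <- function(len_exp, ev_exp, len_unexp, ev_unexp) {
  tibble::tibble(
    person_id = 1L,
    start_day = c(0L, len_exp),
    end_day = c(len_exp - 1L, len_exp + len_unexp - 1L),
    length_days = c(len_exp, len_unexp),
    exposed = c(TRUE, FALSE),
    season = 1L, age_band = 0L,
    n_events = c(ev_exp, ev_unexp)
  )
}

test_that("one era strictly inside observation yields before/during/after intervals", {
  obs <- tibble::tibble(person_id = 1L, start_day = 0L, end_day = 364L)
  eras <- tibble::tibble(person_id = 1L, era_start_day = 100L,
                         era_end_day = 200L)
  ev <- tibble::tibble(person_id = 1L, day = 150L)
  iv <- build_sccs_intervals(obs, eras, ev, seasons = FALSE,
                             age_band_years = NULL)
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$exposed, c(FALSE, TRUE, FALSE))
  expect_equal(iv$n_events, c(0L, 1L, 0L))
  expect_equal(sum(iv$length_days), 365L)
})

test_that("season boundaries add cut points alongside era edges", {
  # observation spans two quarter boundaries (days 91 and 182); the era
  # sits inside the first quarter: five intervals in total
  obs <- tibble::tibble(person_id = 1L, start_day = 0L, end_day = 270L)
  eras <- tibble::tibble(person_id = 1L, era_start_day = 30L,
                         era_end_day = 60L)
  ev <- tibble::tibble(person_id = 1L, day = 40L)
  iv <- build_sccs_intervals(obs, eras, ev, seasons = TRUE,
                             age_band_years = NULL)
  expect_equal(nrow(iv), 5L)
  expect_equal(iv$start_day, c(0L, 30L, 61L, 91L, 182L))
  expect_equal(iv$season, c(1L, 1L, 1L, 2L, 3L))
  expect_equal(sum(iv$length_days), 271L)
})

test_that("intervals exactly partition observation time with all covariates active", {
  sim <- simulate_sccs_data(n_persons = 40, obs_days = 900,
                            baseline_rate = 2e-3, irr = 1.5, seed = 5)
  persons <- tibble::tibble(person_id = 1:40,
                            year_of_birth = sample(1940:1980, 40,
                                                   replace = TRUE))
  co <- list(statin = tibble::tibble(person_id = 1:40,
                                     era_start_day = 200L,
                                     era_end_day = 420L))
  iv <- build_sccs_intervals(sim$observation_periods, sim$eras,
                             sim$events, persons = persons,
                             co_drug_eras = co)
  lens <- iv |>
    dplyr::summarise(l = sum(length_days), .by = person_id)
  expect_true(all(lens$l == 900L))
  expect_equal(sum(iv$n_events), nrow(sim$events))
  expect_true("co_statin" %in% names(iv))

  # events outside observation are a data error
  bad_ev <- tibble::tibble(person_id = 1L, day = 5000L)
  expect_error(build_sccs_intervals(sim$observation_periods, sim$eras,
                                    bad_ev),
               class = "safetysignal_data_error")
})

test_that("the conditional MLE matches the closed form on single-case fixtures", {
  # 100 exposed days with 2 events vs 100 unexposed days with 1 event:
  # 2/3 = 100 e^b / (100 e^b + 100)  =>  IRR = 2
  fit <- fit_sccs(one_case(100L, 2L, 100L, 1L),
                  regularize_covariates = FALSE)
  expect_equal(fit$irr, 2, tolerance = 1e-8)

  # 50 exposed days 1 event vs 150 unexposed days 1 event => IRR = 3
  fit <- fit_sccs(one_case(50L, 1L, 150L, 1L),
                  regularize_covariates = FALSE)
  expect_equal(fit$irr, 3, tolerance = 1e-8)

  # analytic ratio formula on general two-interval data
  fit <- fit_sccs(one_case(80L, 5L, 240L, 3L),
                  regularize_covariates = FALSE)
  expect_equal(fit$log_irr, log((5 / 80) / (3 / 240)), tolerance = 1e-8)
})

test_that("per-person multiplicative frailty leaves the estimate unchanged", {
  iv <- dplyr::bind_rows(
    one_case(100L, 2L, 100L, 1L),
    dplyr::mutate(one_case(60L, 1L, 200L, 2L), person_id = 2L)
  )
  f1 <- fit_sccs(iv, regularize_covariates = FALSE)
  # scaling one person's interval lengths acts exactly like a frailty
  # multiplying that person's rate; the conditional fit must not move
  iv2 <- dplyr::mutate(
    iv, length_days = ifelse(person_id == 1L, length_days * 3.7,
                             length_days))
  f2 <- fit_sccs(iv2, regularize_covariates = FALSE)
  expect_equal(f1$log_irr, f2$log_irr, tolerance = 1e-8)
})

test_that("cases with no exposed time are flagged inestimable", {
  iv <- one_case(100L, 2L, 100L, 1L)
  iv$exposed <- FALSE
  expect_warning(fit <- fit_sccs(iv, regularize_covariates = FALSE),
                 "inestimable")
  expect_false(fit$estimable)
  expect_error(fit_sccs(dplyr::mutate(one_case(10L, 0L, 10L, 0L))),
               class = "safetysignal_estimation_error")
})

test_that("strong between-person frailty does not bias the null", {
  reps <- 20
  betas <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_sccs_data(n_persons = 250, obs_days = 730,
                              baseline_rate = 1.5e-3, irr = 1,
                              frailty_sd = 1, seed = 900 + r)
    iv <- build_sccs_intervals(sim$observation_periods, sim$eras,
                               sim$events, seasons = FALSE,
                               age_band_years = NULL)
    betas[r] <- fit_sccs(iv, regularize_covariates = FALSE)$log_irr
  }
  se_mean <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas)), 3 * se_mean)
})

test_that("the regularized fit is deterministic and recovers a moderate effect", {
  sim <- simulate_sccs_data(n_persons = 400, obs_days = 730,
                            baseline_rate = 2e-3, irr = 2, seed = 44)
  persons <- tibble::tibble(person_id = 1:400,
                            year_of_birth = sample(1940:1985, 400,
                                                   replace = TRUE))
  iv <- build_sccs_intervals(sim$observation_periods, sim$eras,
                             sim$events, persons = persons)
  f1 <- fit_sccs(iv, seed = 3)
  f2 <- fit_sccs(iv, seed = 3)
  expect_identical(f1$log_irr, f2$log_irr)
  expect_identical(f1$selected_penalty, f2$selected_penalty)
  expect_true(f1$estimable)
  # the exposure effect survives nuisance regularization
  expect_lt(abs(f1$log_irr - log(2)), 3 * f1$se)
  expect_s3_class(glance(f1), "tbl_df")
})
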