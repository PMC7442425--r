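test_that("population generation gives exact counts and is reproducible", {
  cfg <- sim_config(n_persons = 1000, seed = 7)
  db1 <- generate_population(cfg)
  expect_equal(nrow(db1$persons), 1000)
  expect_equal(nrow(db1$observation_periods), 1000)
  # exactly one observation period per person
  expect_equal(dplyr::n_distinct(db1$observation_periods$person_id), 1000)

  db2 <- generate_population(cfg)
  expect_identical(db1$persons, db2$persons)
  expect_identical(db1$observation_periods, db2$observation_periods)
  expect_identical(db1$condition_occurrences, db2$condition_occurrences)

  full1 <- simulate_claims(cfg)
  full2 <- simulate_claims(cfg)
  expect_identical(full1$drug_exposures, full2$drug_exposures)
  expect_identical(full1$condition_occurrences, full2$condition_occurrences)
})

test_that("covariate prevalence matches the binomial sampling distribution", {
  cfg <- sim_config(
    n_persons = 100000, seed = 11,
    covariates = tibble::tibble(name = "female", prevalence = 0.8),
    treatment_coefs = c(female = 0),
    outcomes = list(y = list(baseline_hazard = 1e-3, log_hr = 0,
                             covariate_effects = NULL))
  )
  db <- generate_population(cfg)
  p_hat <- mean(db$persons$sex == "female")
  se <- sqrt(0.8 * 0.2 / 100000)
  expect_lt(abs(p_hat - 0.8), 3 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_persons = 0),
               class = "safetysignal_config_error")
  expect_error(
    sim_config(covariates = tibble::tibble(name = "x", prevalence = 1.2),
               treatment_coefs = c(x = 0)),
    class = "safetysignal_config_error"
  )
  expect_error(sim_config(treatment_coefs = c(not_a_covariate = 1)),
               class = "safetysignal_config_error")
  expect_error(
    sim_config(outcomes = list(y = list(baseline_hazard = -1, log_hr = 0))),
    class = "safetysignal_config_error"
  )
})

test_that("neutral treatment model splits arms 50:50", {
  cfg <- null_config(n = 50000, seed = 3)
  db <- assign_treatments(generate_population(cfg))
  share <- mean(db$truth$arm == "target")
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 50000))
})

test_that("logistic regression over simulated data recovers the treatment coefficient", {
  cfg <- sim_config(
    n_persons = 100000, seed = 5,
    covariates = tibble::tibble(name = c("female", "x"),
                                prevalence = c(0.5, 0.5)),
    treatment_intercept = 0,
    treatment_coefs = c(x = 1.0),
    outcomes = list(y = list(baseline_hazard = 1e-3, log_hr = 0,
                             covariate_effects = NULL))
  )
  db <- assign_treatments(generate_population(cfg))
  d <- data.frame(y = as.integer(db$truth$arm == "target"),
                  x = db$truth$covariates$x)
  fit <- glm(y ~ x, family = binomial(), data = d)
  expect_lt(abs(unname(coef(fit)["x"]) - 1.0), 0.1)
})

test_that("deterministic refill schedule yields the expected record count", {
  cfg <- sim_config(
    n_persons = 50, seed = 2,
    exposure = list(days_supplied = 30, n_refills = c(3L, 3L),
                    refill_gap = c(10L, 10L)),
    observation = list(days_before_index = c(400L, 400L),
                       days_after_index = c(1000L, 1000L))
  )
  db <- assign_treatments(generate_population(cfg))
  per_person <- dplyr::count(db$drug_exposures, person_id)
  expect_true(all(per_person$n == 4L)) # initial fill + 3 refills
  # and the era builder stitches them into one era of 4*30 + 3*10 days
  eras <- build_drug_eras(db$drug_exposures)
  expect_true(all(eras$era_end_day - eras$era_start_day + 1L == 150L))
})

test_that("30-day event proportion matches the exponential closed form", {
  cfg <- null_config(n = 100000, seed = 13, log_hr = 0,
                     baseline_hazard = 0.001)
  db <- simulate_claims(cfg)
  idx <- db$truth$index_day
  ev <- dplyr::filter(db$condition_occurrences, condition_code == "y")
  in_window <- ev$day <= idx[ev$person_id] + 30L
  p_hat <- sum(in_window) / cfg$n_persons
  p_true <- 1 - exp(-0.001 * 30) # 0.029554
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("every generated day lies inside the observation period", {
  db <- simulate_claims(confounded_config(n = 2000, seed = 17, n_nc = 5))
  obs <- db$observation_periods
  obs <- dplyr::rename(obs, obs_start = start_day, obs_end = end_day)
  co <- dplyr::inner_join(db$condition_occurrences, obs, by = "person_id")
  expect_true(all(co$day >= co$obs_start & co$day <= co$obs_end))
  dx <- dplyr::inner_join(db$drug_exposures, obs, by = "person_id")
  expect_true(all(dx$start_day >= dx$obs_start))
  expect_true(all(dx$start_day <= dx$obs_end))
  expect_true(all(dx$start_day + dx$days_supplied - 1L <= dx$obs_end))
})

test_that("per-table random streams keep the population stable when outcomes change", {
  base <- sim_config(n_persons = 500, seed = 9, n_negative_controls = 2)
  more <- sim_config(n_persons = 500, seed = 9, n_negative_controls = 20)
  db1 <- simulate_claims(base)
  db2 <- simulate_claims(more)
  expect_identical(db1$persons, db2$persons)
  expect_identical(db1$observation_periods, db2$observation_periods)
  expect_identical(db1$drug_exposures, db2$drug_exposures)
})

test_that("crude Cox recovers the true hazard ratio without confounding", {
  reps <- 20
  betas <- ses <- numeric(reps)
  for (r in seq_len(reps)) {
    db <- simulate_claims(null_config(n = 3000, seed = 100 + r,
                                      log_hr = log(1.5)))
    coh <- select_new_users(db, "target_drug", "comparator_drug")
    ev <- dplyr::filter(db$condition_occurrences, condition_code == "y")
    ri <- compute_time_at_risk(coh, NULL, ev, tar_spec("intention_to_treat"),
                               db$observation_periods)
    res <- fit_stratified_cox(ri, rep(1L, nrow(ri)))
    betas[r] <- res$log_hr
    ses[r] <- res$se_log_hr
  }
  se_mean <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas) - log(1.5)), 3 * se_mean)
})

test_that("claims databases round-trip through the CSV layout", {
  db <- simulate_claims(null_config(n = 200, seed = 4, n_nc = 2))
  dir <- withr::local_tempdir()
  write_claims_db(db, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_claims_db(dir)
  expect_equal(as.data.frame(back$persons), as.data.frame(db$persons))
  expect_equal(as.data.frame(back$drug_exposures),
               as.data.frame(db$drug_exposures))
  expect_equal(as.data.frame(back$condition_occurrences),
               as.data.frame(db$condition_occurrences))
})
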