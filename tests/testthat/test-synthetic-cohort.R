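test_that("covariate generation is seed-deterministic and respects config errors", {
  cfg <- cohort_config(n_subjects = 1000L, n_covariates = 10L, seed = 7L)
  a <- generate_covariates(cfg)
  b <- generate_covariates(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_equal(dim(a$matrix), c(1000L, 10L))
  expect_true(all(a$matrix %in% c(0L, 1L)))
  expect_error(cohort_config(n_subjects = 0L), "n_subjects")
  expect_error(cohort_config(prevalence_range = c(0.5, 0.1)),
               "prevalence_range")
  expect_error(cohort_config(study_end_day = 0L, study_start_day = 0L),
               "study_end_day")
})

test_that("zero latent correlation gives near-independent covariates", {
  cfg <- cohort_config(n_subjects = 2000L, n_covariates = 8L,
                       prevalence_range = c(0.2, 0.4),
                       latent_correlation = 0, seed = 11L)
  x <- generate_covariates(cfg)$matrix
  r <- stats::cor(x)
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(2000))
})

test_that("empirical prevalences stay inside the requested range", {
  cfg <- cohort_config(n_subjects = 20000L, n_covariates = 30L,
                       prevalence_range = c(0.05, 0.30),
                       latent_correlation = 0.3, seed = 5L)
  x <- generate_covariates(cfg)$matrix
  prev <- colMeans(x)
  expect_true(all(prev > 0.03 & prev < 0.33))
  # positive latent correlation induces positive covariate dependence
  r <- stats::cor(x)
  expect_gt(mean(r[upper.tri(r)]), 0)
})

test_that("prescription generation hits the target initiator fraction", {
  cfg <- cohort_config(n_subjects = 20000L, n_covariates = 5L,
                       target_exposure_prevalence = 0.26, seed = 13L)
  x <- generate_covariates(cfg)$matrix
  rx <- generate_prescriptions(x, rep(0, 5), cfg)
  frac <- length(unique(rx$subject_id)) / nrow(x)
  expect_gt(frac, 0.24)
  expect_lt(frac, 0.28)
  expect_true(all(rx$end_day > rx$start_day))
  expect_true(all(rx$start_day >= cfg$study_start_day &
                    rx$end_day <= cfg$study_end_day))
})

test_that("zero target exposure produces no prescriptions", {
  cfg <- cohort_config(n_subjects = 100L, n_covariates = 3L,
                       target_exposure_prevalence = 0, seed = 1L)
  x <- generate_covariates(cfg)$matrix
  rx <- generate_prescriptions(x, rep(0, 3), cfg)
  expect_equal(nrow(rx), 0L)
})

test_that("negative-control event rate matches the exponential closed form", {
  cfg <- cohort_config(n_subjects = 20000L, n_covariates = 4L, n_nco = 2L,
                       nco_baseline_hazard = 5e-4, study_end_day = 1825L,
                       seed = 3L)
  x <- generate_covariates(cfg)$matrix
  ev <- generate_nco_events(x, cfg, hazard_coefficients = matrix(0, 4, 2))
  expected <- 1 - exp(-5e-4 * 1825)
  expect_equal(mean(ev$observed[, 1]), expected, tolerance = 0.02)
  expect_equal(mean(ev$observed[, 2]), expected, tolerance = 0.02)
  # event days lie inside the follow-up window
  d <- ev$event_day[!is.na(ev$event_day)]
  expect_true(all(d >= cfg$study_start_day & d <= cfg$study_end_day))
})

test_that("zero baseline hazard censors everyone", {
  cfg <- cohort_config(n_subjects = 200L, n_covariates = 3L, n_nco = 2L,
                       nco_baseline_hazard = 0, seed = 2L)
  x <- generate_covariates(cfg)$matrix
  ev <- generate_nco_events(x, cfg)
  expect_true(all(ev$observed == 0L))
  expect_true(all(is.na(ev$event_day)))
})

test_that("negative-control generator is null-calibrated against treatment", {
  # treatment labels drawn independently of the event model must show a null
  # hazard ratio: nominal 95% CI coverage across repeated generations
  n_rep <- 60L
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_subjects = 2000L, n_covariates = 6L, n_nco = 1L,
                         nco_baseline_hazard = 4e-4, seed = 1000L + r)
    x <- generate_covariates(cfg)$matrix
    ev <- generate_nco_events(x, cfg)
    set.seed(2000L + r)
    trt <- rbinom(2000L, 1, 0.26)
    time <- ifelse(ev$observed[, 1] == 1L, ev$event_day[, 1], cfg$study_end_day)
    fit <- survival::coxph(survival::Surv(time, ev$observed[, 1]) ~ trt)
    ci <- stats::confint(fit)
    covered[r] <- ci[1] <= 0 && ci[2] >= 0
  }
  band <- stats::qbinom(c(0.025, 0.975), n_rep, 0.95)
  expect_gte(sum(covered), band[1])
  expect_lte(sum(covered), band[2])
})

test_that("base cohort assembles with the documented shape and round-trips CSV", {
  cfg <- cohort_config(n_subjects = 400L, n_covariates = 12L, n_nco = 69L,
                       seed = 21L)
  base <- generate_base_cohort(cfg)
  expect_s3_class(base, "base_cohort")
  expect_equal(ncol(base$nco_event_day), 69L)
  expect_true(all(base$prescriptions$subject_id %in% base$subject_ids))
  expect_length(base$clinical_observed, 400L)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_base_cohort(base, dir1)
  rt <- read_base_cohort_csvs(dir1)
  base2 <- base
  base2$covariates <- as.matrix(rt$covariates[, -1])
  base2$prescriptions <- rt$prescriptions
  write_base_cohort(base2, dir2)
  for (f in c("cohort_covariates.csv", "prescriptions.csv")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7))
  }
})

test_that("identical config and seed reproduce the whole cohort", {
  cfg <- cohort_config(n_subjects = 300L, n_covariates = 10L, n_nco = 4L,
                       seed = 8L)
  a <- generate_base_cohort(cfg)
  b <- generate_base_cohort(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$nco_event_day, b$nco_event_day)
  expect_identical(a$clinical_observed, b$clinical_observed)
})
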