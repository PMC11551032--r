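test_that("intercept calibration solves the mean-probability equation", {
  expect_equal(calibrate_intercept(rep(0, 10), 0.5), 0, tolerance = 1e-8)
  # closed form when the linear predictor is flat
  expect_equal(calibrate_intercept(rep(0, 50), 0.0075),
               log(0.0075 / (1 - 0.0075)), tolerance = 1e-6)
  set.seed(1)
  lp <- rnorm(500, sd = 2)
  a <- calibrate_intercept(lp, 0.0075)
  expect_lt(abs(mean(plogis(a + lp)) - 0.0075), 1e-8)
  a2 <- calibrate_intercept(lp, 0.9)
  expect_lt(abs(mean(plogis(a2 + lp)) - 0.9), 1e-8)
  expect_error(calibrate_intercept(lp, 0), "probability")
  expect_error(calibrate_intercept(lp, 1), "probability")
})

test_that("role selection returns disjoint sets of the requested sizes", {
  set.seed(2)
  x <- matrix(rbinom(200 * 90, 1, 0.2), 200, 90,
              dimnames = list(NULL, sprintf("cov_%03d", 1:90)))
  t_lab <- rbinom(200, 1, 0.3)
  y_lab <- rbinom(200, 1, 0.1)
  roles <- select_covariate_roles(x, t_lab, y_lab, sizes = c(50L, 20L, 20L),
                                  seed = 4L)
  expect_length(roles$confounders, 50L)
  expect_length(roles$instruments, 20L)
  expect_length(roles$risk_factors, 20L)
  all_names <- c(roles$confounders, roles$instruments, roles$risk_factors)
  expect_equal(length(unique(all_names)), 90L)

  expect_error(select_covariate_roles(x[, 1:3], t_lab, y_lab,
                                      sizes = c(2L, 1L, 1L)),
               "exceed")
  r1 <- select_covariate_roles(x, strategy = "random", sizes = c(5L, 3L, 3L),
                               seed = 9L)
  r2 <- select_covariate_roles(x, strategy = "random", sizes = c(5L, 3L, 3L),
                               seed = 9L)
  expect_identical(r1, r2)
})

test_that("association-ranked roles pick up the genuinely dual-association covariates", {
  # covariates 1-3 drive both labels, 4-5 exposure only, 6-7 outcome only
  set.seed(5)
  n <- 4000
  x <- matrix(rbinom(n * 12, 1, 0.3), n, 12,
              dimnames = list(NULL, sprintf("cov_%03d", 1:12)))
  t_lab <- rbinom(n, 1, plogis(-1 + 1.5 * rowSums(x[, 1:3]) + 1.5 * rowSums(x[, 4:5])))
  y_lab <- rbinom(n, 1, plogis(-2 + 1.5 * rowSums(x[, 1:3]) + 1.5 * rowSums(x[, 6:7])))
  roles <- select_covariate_roles(x, t_lab, y_lab, sizes = c(3L, 2L, 2L),
                                  seed = 1L)
  expect_setequal(roles$confounders, sprintf("cov_%03d", 1:3))
  expect_setequal(roles$instruments, sprintf("cov_%03d", 4:5))
  expect_setequal(roles$risk_factors, sprintf("cov_%03d", 6:7))
})

test_that("derived coefficients respect role support and recover known truths", {
  # role support: instruments get zero outcome coefficients and risk factors
  # zero exposure coefficients by construction of the named vectors
  set.seed(6)
  n <- 30000
  p <- 10
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, sprintf("cov_%03d", 1:p)))
  roles <- list(confounders = sprintf("cov_%03d", 1:4),
                instruments = sprintf("cov_%03d", 5:6),
                risk_factors = sprintf("cov_%03d", 7:8))
  class(roles) <- "role_assignment"
  b_t <- c(0.8, -0.5, 0.6, 0.4, 0.7, -0.6)
  b_y <- c(0.5, 0.5, -0.7, 0.3, 0.6, 0.8)
  t_lab <- rbinom(n, 1, plogis(-1 + drop(x[, 1:6] %*% b_t)))
  y_lab <- rbinom(n, 1, plogis(-2 + drop(x[, c(1:4, 7:8)] %*% b_y)))
  base <- list(covariates = x, subject_ids = seq_len(n),
               clinical_observed = y_lab)
  cohort <- data.frame(subject_id = seq_len(n), treated = t_lab)
  co <- derive_coefficients(base, cohort, roles)
  expect_setequal(names(co$exposure_coefficients),
                  c(roles$confounders, roles$instruments))
  expect_setequal(names(co$outcome_coefficients),
                  c(roles$confounders, roles$risk_factors))
  # parameter recovery within ~2 SEs at this n (SE ~ 0.03)
  expect_equal(unname(co$exposure_coefficients[sprintf("cov_%03d", 1:6)]),
               b_t, tolerance = 0.12)
  expect_equal(unname(co$outcome_coefficients[sprintf("cov_%03d", c(1:4, 7:8))]),
               b_y, tolerance = 0.12)
})

test_that("replicates are reproducible, right-sized and drawn from base rows", {
  set.seed(8)
  x <- matrix(rbinom(500 * 6, 1, 0.3), 500, 6,
              dimnames = list(NULL, sprintf("cov_%03d", 1:6)))
  roles <- list(confounders = "cov_001", instruments = "cov_002",
                risk_factors = "cov_003")
  spec <- plasmode_spec(n_resample = 1000L, n_replicates = 3L,
                        exposure_coefficients = c(cov_001 = 0.5, cov_002 = 0.5),
                        outcome_coefficients = c(cov_001 = 0.5, cov_003 = 0.5),
                        target_outcome_risk = 0.05, seed = 17L)
  r1 <- simulate_replicate(x, roles, spec, 1L)
  r1b <- simulate_replicate(x, roles, spec, 1L)
  r2 <- simulate_replicate(x, roles, spec, 2L)
  expect_identical(r1$treatment, r1b$treatment)
  expect_identical(r1$outcome, r1b$outcome)
  expect_false(identical(r1$treatment, r2$treatment))
  expect_equal(nrow(r1$covariates), 1000L)
  # every replicate row equals some base row
  key <- apply(x, 1, paste, collapse = "")
  expect_true(all(apply(r1$covariates, 1, paste, collapse = "") %in% key))
  expect_error(simulate_replicate(x, roles,
                                  within(spec, n_resample <- 0L), 1L))

  reps <- run_plasmode(x, roles, spec)
  expect_length(reps, 3L)
  expect_equal(length(unique(sapply(reps, `[[`, "replicate_seed"))), 3L)
})

test_that("null generating model yields a null treatment-outcome association", {
  set.seed(9)
  x <- matrix(rbinom(2000 * 4, 1, 0.3), 2000, 4,
              dimnames = list(NULL, sprintf("cov_%03d", 1:4)))
  roles <- list(confounders = character(0), instruments = character(0),
                risk_factors = character(0))
  spec <- plasmode_spec(n_resample = 5000L, n_replicates = 100L,
                        true_beta_t = 0, target_outcome_risk = 0.05,
                        exposure_coefficients = numeric(0),
                        outcome_coefficients = numeric(0), seed = 23L)
  covered <- sapply(seq_len(spec$n_replicates), function(k) {
    r <- simulate_replicate(x, roles, spec, k)
    e <- estimate_logor(r$treatment, r$outcome)
    e$estimable && e$ci_low <= 0 && e$ci_high >= 0
  })
  band <- stats::qbinom(c(0.025, 0.975), length(covered), 0.95)
  expect_gte(sum(covered), band[1])
  expect_lte(sum(covered), band[2])
})

test_that("pooled treatment and outcome rates match their calibration targets", {
  set.seed(10)
  x <- matrix(rbinom(1000 * 6, 1, 0.25), 1000, 6,
              dimnames = list(NULL, sprintf("cov_%03d", 1:6)))
  roles <- list(confounders = sprintf("cov_%03d", 1:2),
                instruments = "cov_003", risk_factors = "cov_004")
  spec <- plasmode_spec(n_resample = 2000L, n_replicates = 50L,
                        true_beta_t = log(2),
                        target_exposure_prevalence = 0.26,
                        target_outcome_risk = 0.0075,
                        exposure_coefficients = c(cov_001 = 0.5, cov_002 = -0.4,
                                                  cov_003 = 0.6),
                        outcome_coefficients = c(cov_001 = 0.5, cov_002 = 0.4,
                                                 cov_004 = 0.7),
                        seed = 31L)
  rates <- sapply(seq_len(spec$n_replicates), function(k) {
    r <- simulate_replicate(x, roles, spec, k)
    c(mean(r$treatment), mean(r$outcome))
  })
  expect_lt(abs(mean(rates[1, ]) - 0.26) / 0.26, 0.05)
  expect_lt(abs(mean(rates[2, ]) - 0.0075) / 0.0075, 0.20)
})

test_that("the injected treatment effect is recoverable by the true outcome model", {
  set.seed(11)
  p <- 8
  x <- matrix(rbinom(3000 * p, 1, 0.3), 3000, p,
              dimnames = list(NULL, sprintf("cov_%03d", 1:p)))
  roles <- list(confounders = sprintf("cov_%03d", 1:3),
                instruments = sprintf("cov_%03d", 4:5),
                risk_factors = sprintf("cov_%03d", 6:7))
  w_t <- c(0.6, 0.6, 0.6, 0.8, 0.8)
  names(w_t) <- c(roles$confounders, roles$instruments)
  w_y <- c(0.7, 0.7, 0.7, 0.6, 0.6)
  names(w_y) <- c(roles$confounders, roles$risk_factors)
  spec <- plasmode_spec(n_resample = 60000L, n_replicates = 1L,
                        true_beta_t = log(2), target_outcome_risk = 0.05,
                        exposure_coefficients = w_t,
                        outcome_coefficients = w_y, seed = 37L)
  r <- simulate_replicate(x, roles, spec, 1L)
  d <- data.frame(y = r$outcome, t = r$treatment,
                  r$covariates[, c(roles$confounders, roles$risk_factors)])
  fit <- stats::glm(y ~ ., data = d, family = stats::binomial())
  co <- summary(fit)$coefficients
  expect_lt(abs(co["t", "Estimate"] - log(2)), 2 * co["t", "Std. Error"])
})
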