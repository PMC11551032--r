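test_that("Brier score matches hand-computed values and validates input", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.2), c(1, 0)), 0.04)
  expect_error(brier_score(c(0.5, 0.5), 1), "lengths")
  expect_error(brier_score(c(1.5, 0.5), c(1, 0)), "0, 1")
})

test_that("grid search picks the single candidate, deterministically, and beats the rest", {
  d <- make_ps_data(2000, 5, rep(0.8, 5), seed = 2)
  cfg1 <- score_model_config("lasso", "ps", hyper_grid = list(lambda = 0.01),
                             cv_folds = 5L, seed = 3L)
  t1 <- tune_hyperparameters(d$covariates, d$treatment, cfg1)
  expect_equal(t1$chosen$lambda, 0.01)

  cfg <- score_model_config("lasso", "ps",
                            hyper_grid = list(lambda = c(0.2, 0.01, 0.001)),
                            cv_folds = 5L, seed = 3L)
  ta <- tune_hyperparameters(d$covariates, d$treatment, cfg)
  tb <- tune_hyperparameters(d$covariates, d$treatment, cfg)
  expect_identical(ta$chosen, tb$chosen)
  expect_identical(ta$audit$cv_brier, tb$audit$cv_brier)
  # the winner attains the fold-minimum over the whole grid by construction
  expect_equal(ta$cv_brier, min(ta$audit$cv_brier))
})

test_that("reference propensity scores track the true model", {
  d <- make_ps_data(20000, 8, c(rep(1, 4), rep(0, 4)), seed = 4)
  cfg <- score_model_config("reference", "ps",
                            confounder_names = colnames(d$covariates)[1:4],
                            seed = 5L)
  fit <- fit_propensity(d, cfg)
  expect_gt(stats::cor(fit$scores, d$true_ps), 0.95)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  # calibration-in-the-large: mean score equals treatment prevalence
  expect_equal(mean(fit$scores), mean(d$treatment), tolerance = 1e-6)
})

test_that("constant covariates collapse the propensity to the prevalence", {
  x <- matrix(1L, 500, 2, dimnames = list(NULL, c("a", "b")))
  set.seed(6)
  t_vec <- rbinom(500, 1, 0.3)
  cfg <- score_model_config("reference", "ps", confounder_names = c("a", "b"))
  fit <- fit_propensity(list(covariates = x, treatment = t_vec), cfg)
  expect_equal(unname(fit$scores), rep(mean(t_vec), 500), tolerance = 1e-6)
})

test_that("single-class treatment is rejected", {
  x <- matrix(rbinom(100, 1, 0.5), 50, 2, dimnames = list(NULL, c("a", "b")))
  cfg <- score_model_config("reference", "ps", confounder_names = "a")
  expect_error(fit_propensity(list(covariates = x,
                                   treatment = rep(1L, 50)), cfg),
               "single-class")
})

test_that("full-cohort DRS forces treatment to zero", {
  set.seed(7)
  n <- 8000
  x <- matrix(rbinom(n * 4, 1, 0.3), n, 4,
              dimnames = list(NULL, sprintf("c%d", 1:4)))
  t_vec <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-2.5 + 1.5 * t_vec + 0.8 * x[, 1]))
  data <- list(covariates = x, treatment = t_vec, outcome = y)
  cfg <- score_model_config("reference", "drs_full",
                            confounder_names = colnames(x))
  fit <- fit_drs_full(data, cfg)
  # with a strongly positive treatment effect, forcing T=0 lowers the
  # predicted risk for every treated subject
  expect_true(all(fit$scores[t_vec == 1] < fit$scores_observed_t[t_vec == 1]))
  # calibration-in-the-large at the observed treatment
  expect_equal(mean(fit$scores_observed_t), mean(y), tolerance = 1e-6)
})

test_that("DRS on outcome independent of everything approaches the event rate", {
  set.seed(8)
  n <- 20000
  x <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  t_vec <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, 0.05)
  cfg <- score_model_config("reference", "drs_full",
                            confounder_names = colnames(x))
  fit <- fit_drs_full(list(covariates = x, treatment = t_vec, outcome = y),
                      cfg)
  expect_lt(max(abs(fit$scores - mean(y))), 0.02)
})

test_that("reference DRS is consistent for the true rare-outcome model", {
  set.seed(9)
  n <- 50000
  x <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  t_vec <- rbinom(n, 1, 0.3)
  truth0 <- plogis(-5 + 0.8 * x[, 1] + 0.5 * x[, 2])
  y <- rbinom(n, 1, plogis(-5 + 0.8 * x[, 1] + 0.5 * x[, 2] + 0.7 * t_vec))
  cfg <- score_model_config("reference", "drs_full",
                            confounder_names = colnames(x))
  fit <- fit_drs_full(list(covariates = x, treatment = t_vec, outcome = y),
                      cfg)
  expect_lt(mean(abs(fit$scores - truth0)), 0.002)
})

test_that("unexposed DRS ignores treated subjects' outcomes", {
  set.seed(10)
  n <- 2000
  x <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  t_vec <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-2 + x[, 1]))
  cfg <- score_model_config("reference", "drs_unexposed",
                            confounder_names = colnames(x))
  f1 <- fit_drs_unexposed(list(covariates = x, treatment = t_vec,
                               outcome = y), cfg)
  y2 <- y
  y2[t_vec == 1] <- 1L - y2[t_vec == 1] # perturb treated outcomes only
  f2 <- fit_drs_unexposed(list(covariates = x, treatment = t_vec,
                               outcome = y2), cfg)
  expect_identical(f1$scores, f2$scores)
  expect_error(fit_drs_unexposed(list(covariates = x, treatment = t_vec,
                                      outcome = ifelse(t_vec == 0, 0L, y)),
                                 cfg),
               "unexposed")
})

test_that("zero outcome events abort DRS fitting with advice", {
  x <- matrix(rbinom(200, 1, 0.5), 100, 2, dimnames = list(NULL, c("a", "b")))
  cfg <- score_model_config("reference", "drs_full", confounder_names = "a")
  expect_error(fit_drs_full(list(covariates = x,
                                 treatment = rbinom(100, 1, 0.5),
                                 outcome = rep(0L, 100)), cfg),
               "larger cohort")
})

test_that("data-driven methods share the uniform contract on one data set", {
  d <- make_ps_data(800, 6, c(rep(0.8, 3), rep(0, 3)), seed = 11)
  grids <- list(
    lasso = list(lambda = c(0.05, 0.005)),
    xgboost = list(nrounds = 30L, max_depth = c(2L, 3L),
                   learning_rate = 0.3, min_child_weight = 1,
                   subsample = 1.0),
    mlp = list(size = 3L, decay = 0.1, maxit = 60L))
  for (method in names(grids)) {
    cfg <- score_model_config(method, "ps", hyper_grid = grids[[method]],
                              cv_folds = 3L, seed = 12L)
    fit <- fit_score_model(d, cfg)
    expect_s3_class(fit, "fitted_score_model")
    expect_true(all(fit$scores >= 0 & fit$scores <= 1))
    expect_true(fit$cv_brier >= 0 && fit$cv_brier <= 1)
    expect_gt(stats::cor(fit$scores, d$true_ps), 0.5)
    # chosen candidate attains the minimum CV Brier on the shared folds
    expect_equal(fit$cv_brier, min(fit$tuning_audit$cv_brier))
    # determinism of the full fit
    fit2 <- fit_score_model(d, cfg)
    expect_equal(fit$scores, fit2$scores, tolerance = 1e-12)
  }
})

test_that("failed candidates are skipped with infinite Brier", {
  d <- make_ps_data(300, 4, rep(0.5, 4), seed = 13)
  cfg <- score_model_config("mlp", "ps",
                            hyper_grid = list(size = c(-5L, 2L), decay = 0.1,
                                              maxit = 30L),
                            cv_folds = 3L, seed = 14L)
  expect_message(t1 <- tune_hyperparameters(d$covariates, d$treatment, cfg),
                 "failed")
  expect_true(is.infinite(t1$audit$cv_brier[t1$audit$size == -5L]))
  expect_equal(t1$chosen$size, 2L)
})
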