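# Score estimation: propensity scores and disease risk scores via four model
# families (reference logistic regression on known confounders, L1-penalised
# logistic regression, gradient-boosted trees, multi-layer perceptron), each
# tuned by 10-fold cross-validation minimising the mean Brier score.

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary labels;
#' the cross-validation tuning criterion.
#'
#' @param predicted Probability vector in [0, 1].
#' @param observed Binary vector of the same length.
#' @return Nonnegative scalar in [0, 1].
#' @export
brier_score <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_config("predicted and observed lengths differ (%d vs %d)",
                length(predicted), length(observed))
  }
  if (any(predicted < 0 | predicted > 1)) {
    stop_config("predictions must lie in [0, 1]")
  }
  mean((predicted - as.numeric(observed))^2)
}

#' Score-model configuration
#'
#' @param method One of \code{"reference"}, \code{"lasso"}, \code{"xgboost"},
#'   \code{"mlp"}.
#' @param target One of \code{"ps"} (propensity score, P(T=1|X)),
#'   \code{"drs_full"} (full-cohort disease risk score: outcome model on
#'   covariates + treatment fitted to everyone, predicted at T=0) or
#'   \code{"drs_unexposed"} (outcome model fitted on the untreated only,
#'   predicted for all).
#' @param confounder_names Character vector of covariate names; required for
#'   the reference method (its clinically informed confounder set), ignored
#'   by the data-driven methods, which take all covariates as input.
#' @param hyper_grid Named list of candidate values, expanded into a full
#'   factorial grid. \code{NULL} uses the method's default grid; the
#'   reference method has no hyperparameters.
#' @param cv_folds Number of cross-validation folds; default 10.
#' @param seed Seed controlling the fold partition and model-fit randomness.
#' @return Object of class \code{score_model_config}.
#' @export
score_model_config <- function(method = c("reference", "lasso", "xgboost", "mlp"),
                               target = c("ps", "drs_full", "drs_unexposed"),
                               confounder_names = NULL, hyper_grid = NULL,
                               cv_folds = 10L, seed = 1L) {
  method <- match.arg(method)
  target <- match.arg(target)
  if (cv_folds < 2L) stop_config("cv_folds must be >= 2")
  if (method == "reference" && is.null(confounder_names)) {
    stop_config("reference method requires confounder_names")
  }
  out <- list(method = method, target = target,
              confounder_names = confounder_names, hyper_grid = hyper_grid,
              cv_folds = as.integer(cv_folds), tuning_metric = "brier",
              seed = as.integer(seed))
  class(out) <- "score_model_config"
  out
}

default_hyper_grid <- function(method, X, y) {
  switch(method,
    reference = list(),
    lasso = {
      # 20 log-spaced penalties from lambda_max (smallest penalty that zeroes
      # every coefficient) down to 1e-4 * lambda_max
      lmax <- max(abs(crossprod(scale(X), y - mean(y)))) / length(y)
      list(lambda = exp(seq(log(lmax), log(1e-4 * lmax), length.out = 20)))
    },
    xgboost = list(nrounds = c(100L, 300L), max_depth = c(3L, 6L),
                   learning_rate = c(0.05, 0.1), min_child_weight = c(1, 10),
                   subsample = c(0.7, 1.0)),
    mlp = list(size = c(4L, 16L), decay = c(0.01, 0.1), maxit = c(50L, 150L)))
}

# fit one model family with fixed hyperparameters; returns an object with a
# score_predict method
fit_backend <- function(method, X, y, params, seed) {
  set.seed(seed)
  model <- switch(method,
    reference = {
      fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                                             family = stats::binomial()))
      co <- fit$coefficients
      co[!is.finite(co)] <- 0
      list(coef = co)
    },
    lasso = {
      # warm-started path down to the requested penalty: much faster and
      # more stable than a cold single-lambda fit, identical optimum
      lam <- params$lambda
      path <- exp(seq(log(lam) + log(1e3), log(lam), length.out = 25L))
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                            lambda = path, standardize = TRUE)
      list(fit = fit, lambda = lam)
    },
    xgboost = xgboost::xgboost(
      X, factor(y, levels = c(0, 1)), objective = "binary:logistic",
      nrounds = params$nrounds, max_depth = params$max_depth,
      learning_rate = params$learning_rate,
      min_child_weight = params$min_child_weight,
      subsample = params$subsample, nthreads = 1L, seed = seed,
      verbosity = 0L),
    mlp = nnet::nnet(x = X, y = y, size = params$size, decay = params$decay,
                     maxit = params$maxit, entropy = TRUE, trace = FALSE,
                     MaxNWts = 100000L))
  structure(list(method = method, model = model), class = "score_backend")
}

score_predict <- function(backend, X) {
  p <- switch(backend$method,
    reference = expit(drop(cbind(1, X) %*% backend$model$coef)),
    lasso = drop(stats::predict(backend$model$fit, X, type = "response",
                                s = backend$model$lambda)),
    xgboost = stats::predict(backend$model, X, type = "response"),
    mlp = drop(stats::predict(backend$model, X)))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Tune hyperparameters by cross-validated Brier score
#'
#' Exhaustive search over the factorial expansion of \code{hyper_grid}: for
#' each candidate, models are fitted on k-1 folds of a fixed seeded
#' \code{cv_folds}-fold partition and evaluated on the held-out fold; the
#' candidate with the lowest mean fold Brier score wins, ties broken by grid
#' order. Candidates that fail to fit are recorded with infinite Brier score
#' and skipped with a message.
#'
#' @param X Numeric predictor matrix.
#' @param y Binary response vector.
#' @param config A \code{score_model_config}.
#' @return List with \code{chosen} (named list of hyperparameters),
#'   \code{cv_brier} (its mean fold Brier score) and \code{audit}
#'   (data.frame of every candidate with its mean fold Brier).
#' @export
tune_hyperparameters <- function(X, y, config) {
  grid_spec <- config$hyper_grid %||% default_hyper_grid(config$method, X, y)
  if (config$method == "reference" || length(grid_spec) == 0L) {
    return(list(chosen = list(), cv_brier = NA_real_,
                audit = data.frame(cv_brier = numeric(0))))
  }
  grid <- expand.grid(grid_spec, KEEP.OUT.ATTRS = FALSE)
  set.seed(derive_seed(config$seed, "cv_folds"))
  folds <- sample(rep_len(seq_len(config$cv_folds), length(y)))

  if (config$method == "lasso" && identical(names(grid), "lambda")) {
    # one warm-started regularisation path per fold covers every candidate
    lam <- grid$lambda
    ord <- order(lam, decreasing = TRUE)
    fold_b <- matrix(NA_real_, config$cv_folds, nrow(grid))
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 1,
                            lambda = lam[ord], standardize = TRUE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE],
                             type = "response", s = lam)
      fold_b[k, ] <- apply(pred, 2, function(p)
        brier_score(pmin(pmax(p, 0), 1), y[!tr]))
    }
    briers <- colMeans(fold_b)
    best <- which.min(briers)
    return(list(chosen = list(lambda = lam[best]), cv_brier = briers[best],
                audit = cbind(grid, cv_brier = briers)))
  }

  briers <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    fold_b <- rep(NA_real_, config$cv_folds)
    ok <- TRUE
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      b <- tryCatch({
        bk <- fit_backend(config$method, X[tr, , drop = FALSE], y[tr], params,
                          derive_seed(config$seed, "cv_fit", g * 1000L + k))
        brier_score(score_predict(bk, X[!tr, , drop = FALSE]), y[!tr])
      }, error = function(e) NA_real_)
      if (is.na(b)) { ok <- FALSE; break }
      fold_b[k] <- b
    }
    if (!ok) {
      message(sprintf("candidate %d failed to fit; skipped", g))
      briers[g] <- Inf
    } else {
      briers[g] <- mean(fold_b)
    }
  }
  best <- which.min(briers) # ties: first in grid order
  list(chosen = as.list(grid[best, , drop = FALSE]),
       cv_brier = briers[best],
       audit = cbind(grid, cv_brier = briers))
}

# resolve the predictor matrix for a config: reference restricts to its
# confounder list, data-driven methods use every covariate
design_matrix <- function(covariates, config) {
  if (config$method == "reference") {
    missing <- setdiff(config$confounder_names, colnames(covariates))
    if (length(missing)) {
      stop_config("confounder_names not in covariates: %s",
                  paste(utils::head(missing, 3), collapse = ", "))
    }
    covariates[, config$confounder_names, drop = FALSE]
  } else {
    covariates
  }
}

new_fitted_score_model <- function(scores, tuned, config) {
  out <- list(scores = scores, chosen_hyperparameters = tuned$chosen,
              cv_brier = tuned$cv_brier, tuning_audit = tuned$audit,
              method = config$method, target = config$target)
  class(out) <- "fitted_score_model"
  out
}

#' @export
print.fitted_score_model <- function(x, ...) {
  cat(sprintf("<fitted_score_model> method=%s target=%s n=%d cv_brier=%s\n",
              x$method, x$target, length(x$scores),
              format(x$cv_brier, digits = 4)))
  invisible(x)
}

#' Fit a propensity-score model
#'
#' Tunes (for the data-driven methods), refits on the full data and returns
#' in-sample predicted treatment probabilities for every subject.
#'
#' @param data List with \code{covariates} (matrix) and \code{treatment}
#'   (binary vector); a \code{plasmode_replicate} works directly.
#' @param config A \code{score_model_config} with \code{target = "ps"}.
#' @return A \code{fitted_score_model} with scores = P(T=1|X).
#' @export
fit_propensity <- function(data, config) {
  t_vec <- data$treatment
  if (length(unique(t_vec)) < 2L) {
    stop_config("treatment is single-class; propensity model not identifiable")
  }
  X <- design_matrix(data$covariates, config)
  tuned <- tune_hyperparameters(X, t_vec, config)
  bk <- fit_backend(config$method, X, t_vec, tuned$chosen,
                    derive_seed(config$seed, "final_fit"))
  new_fitted_score_model(score_predict(bk, X), tuned, config)
}

#' Fit a full-cohort disease risk score model
#'
#' Fits the outcome on covariates plus treatment over the whole cohort, then
#' predicts every subject's outcome probability with the treatment feature
#' forced to 0: the full-cohort DRS, P(Y=1 | X, T=0).
#'
#' @param data List with \code{covariates}, \code{treatment}, \code{outcome}.
#' @param config A \code{score_model_config} with \code{target = "drs_full"}.
#' @return A \code{fitted_score_model}.
#' @export
fit_drs_full <- function(data, config) {
  y <- data$outcome
  if (sum(y) == 0L) {
    stop_config(paste("no outcome events: disease risk score not estimable;",
                      "use a larger cohort or a higher target outcome risk"))
  }
  X <- cbind(design_matrix(data$covariates, config),
             treatment = as.numeric(data$treatment))
  tuned <- tune_hyperparameters(X, y, config)
  bk <- fit_backend(config$method, X, y, tuned$chosen,
                    derive_seed(config$seed, "final_fit"))
  X0 <- X
  X0[, "treatment"] <- 0
  fm <- new_fitted_score_model(score_predict(bk, X0), tuned, config)
  fm$scores_observed_t <- score_predict(bk, X)
  fm
}

#' Fit an unexposed-population disease risk score model
#'
#' Fits the outcome on covariates using untreated subjects only, then extends
#' the model to the entire population: the unexposed DRS.
#'
#' @param data List with \code{covariates}, \code{treatment}, \code{outcome}.
#' @param config A \code{score_model_config} with
#'   \code{target = "drs_unexposed"}.
#' @return A \code{fitted_score_model}.
#' @export
fit_drs_unexposed <- function(data, config) {
  unexp <- data$treatment == 0
  if (sum(data$outcome[unexp]) == 0L) {
    stop_config("no events among the unexposed; unexposed DRS not estimable")
  }
  X <- design_matrix(data$covariates, config)
  Xu <- X[unexp, , drop = FALSE]
  yu <- data$outcome[unexp]
  tuned <- tune_hyperparameters(Xu, yu, config)
  bk <- fit_backend(config$method, Xu, yu, tuned$chosen,
                    derive_seed(config$seed, "final_fit"))
  new_fitted_score_model(score_predict(bk, X), tuned, config)
}

#' Fit any score model through one uniform interface
#'
#' Dispatches on \code{config$target} to \code{\link{fit_propensity}},
#' \code{\link{fit_drs_full}} or \code{\link{fit_drs_unexposed}}, so the
#' matching and evaluation layers are method- and target-agnostic.
#'
#' @param data List with \code{covariates}, \code{treatment} and (for DRS
#'   targets) \code{outcome}.
#' @param config A \code{score_model_config}.
#' @return A \code{fitted_score_model}.
#' @export
fit_score_model <- function(data, config) {
  switch(config$target,
         ps = fit_propensity(data, config),
         drs_full = fit_drs_full(data, config),
         drs_unexposed = fit_drs_unexposed(data, config),
         stop_config("unknown target '%s'", config$target))
}
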