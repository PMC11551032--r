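# Plasmode simulation: resample observed covariate rows with replacement and
# simulate treatment and a rare binary outcome from logistic models with a
# known, injected treatment effect beta_t.

#' Assign confounder / instrument / risk-factor roles to covariates
#'
#' Splits covariates into three disjoint role sets. The default
#' \code{"association"} strategy ranks covariates by their univariate
#' log-odds associations with the observed exposure and outcome labels:
#' confounders are the covariates with the largest product of absolute
#' exposure and outcome associations, instruments the strongest remaining
#' exposure-only associations, risk factors the strongest remaining
#' outcome-only associations. A \code{"random"} strategy draws the sets
#' uniformly, for null experiments.
#'
#' @param base_covariates Binary matrix with column names.
#' @param exposure_labels Binary vector (observed treatment).
#' @param outcome_labels Binary vector (observed reference outcome).
#' @param sizes Integer triple (confounders, instruments, risk factors);
#'   default \code{c(50, 20, 20)}.
#' @param seed Integer seed (used by both strategies).
#' @param strategy \code{"association"} (default) or \code{"random"}.
#' @return List of class \code{role_assignment} with character vectors
#'   \code{confounders}, \code{instruments}, \code{risk_factors}.
#' @export
select_covariate_roles <- function(base_covariates, exposure_labels = NULL,
                                   outcome_labels = NULL,
                                   sizes = c(50L, 20L, 20L), seed = 1L,
                                   strategy = c("association", "random")) {
  strategy <- match.arg(strategy)
  nm <- colnames(base_covariates)
  p <- length(nm)
  sizes <- as.integer(sizes)
  if (sum(sizes) > p) {
    stop_config("role sizes (%d) exceed available covariates (%d)",
                sum(sizes), p)
  }
  set.seed(derive_seed(seed, "roles"))
  if (strategy == "random" || is.null(exposure_labels) ||
      is.null(outcome_labels)) {
    perm <- sample.int(p)
    conf <- nm[perm[seq_len(sizes[1])]]
    inst <- nm[perm[sizes[1] + seq_len(sizes[2])]]
    risk <- nm[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]]
  } else {
    a_t <- abs(univariate_logodds(base_covariates, exposure_labels))
    a_y <- abs(univariate_logodds(base_covariates, outcome_labels))
    conf_idx <- order(a_t * a_y, decreasing = TRUE)[seq_len(sizes[1])]
    rest <- setdiff(seq_len(p), conf_idx)
    inst_idx <- rest[order(a_t[rest], decreasing = TRUE)[seq_len(sizes[2])]]
    rest <- setdiff(rest, inst_idx)
    risk_idx <- rest[order(a_y[rest], decreasing = TRUE)[seq_len(sizes[3])]]
    conf <- nm[conf_idx]; inst <- nm[inst_idx]; risk <- nm[risk_idx]
  }
  out <- list(confounders = conf, instruments = inst, risk_factors = risk)
  class(out) <- "role_assignment"
  out
}

# univariate log odds ratio of y on each covariate column, with a 0.5
# continuity correction on the 2x2 cells
univariate_logodds <- function(x, y) {
  y <- as.numeric(y)
  n1 <- colSums(x); n0 <- nrow(x) - n1
  e1 <- drop(crossprod(x, y)); e0 <- sum(y) - e1
  log(((e1 + 0.5) * (n0 - e0 + 0.5)) / ((n1 - e1 + 0.5) * (e0 + 0.5)))
}

#' Plasmode simulation settings
#'
#' @param n_resample Rows per replicate (drawn with replacement from the base
#'   covariate matrix).
#' @param n_replicates Number of replicates; default 100.
#' @param true_beta_t Injected treatment effect on the log-odds scale;
#'   default \code{log(2)} (odds ratio 2).
#' @param target_exposure_prevalence Marginal treatment probability target;
#'   default 0.26.
#' @param target_outcome_risk Marginal outcome risk target (given the
#'   realised treatment mix); default 0.0075.
#' @param exposure_coefficients Named log-odds vector over confounders and
#'   instruments.
#' @param outcome_coefficients Named log-odds vector over confounders and
#'   risk factors.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Object of class \code{plasmode_spec}.
#' @export
plasmode_spec <- function(n_resample, n_replicates = 100L,
                          true_beta_t = log(2),
                          target_exposure_prevalence = 0.26,
                          target_outcome_risk = 0.0075,
                          exposure_coefficients, outcome_coefficients,
                          seed = 1L) {
  stopifnot(n_resample >= 1L, n_replicates >= 1L,
            target_outcome_risk > 0, target_outcome_risk < 1,
            target_exposure_prevalence > 0, target_exposure_prevalence < 1)
  out <- list(n_resample = as.integer(n_resample),
              n_replicates = as.integer(n_replicates),
              true_beta_t = true_beta_t,
              target_exposure_prevalence = target_exposure_prevalence,
              target_outcome_risk = target_outcome_risk,
              exposure_coefficients = exposure_coefficients,
              outcome_coefficients = outcome_coefficients,
              seed = as.integer(seed))
  class(out) <- "plasmode_spec"
  out
}

#' Derive plasmode generating coefficients from observed data
#'
#' Fits a logistic model of the observed treatment on confounders and
#' instruments, and of an observed (or stand-in) binary outcome on
#' confounders and risk factors, then zeroes every coefficient outside the
#' respective role support. This transfers realistic association magnitudes
#' from the base cohort into the plasmode generating models. Ridge-stabilised
#' fits (small L2 penalty via \code{glmnet}) are used as a fallback when the
#' plain fit fails to converge or separates.
#'
#' @param base A \code{base_cohort}.
#' @param cohort data.frame from \code{\link{assign_exposure}} (supplies the
#'   observed treatment labels).
#' @param roles A \code{role_assignment}.
#' @param outcome_labels Optional binary vector used as the reference outcome;
#'   defaults to the first negative-control outcome's event indicator.
#' @return List with named vectors \code{exposure_coefficients} (support:
#'   confounders + instruments) and \code{outcome_coefficients} (support:
#'   confounders + risk factors).
#' @export
derive_coefficients <- function(base, cohort, roles, outcome_labels = NULL) {
  x <- base$covariates
  t_obs <- cohort$treated[match(base$subject_ids, cohort$subject_id)]
  if (is.null(outcome_labels)) {
    outcome_labels <- base$clinical_observed %||% base$nco_observed[, 1]
  }
  exp_sup <- c(roles$confounders, roles$instruments)
  out_sup <- c(roles$confounders, roles$risk_factors)
  fit_support <- function(y, support) {
    xs <- x[, support, drop = FALSE]
    co <- tryCatch({
      fit <- suppressWarnings(stats::glm.fit(cbind(1, xs), y,
                                             family = stats::binomial()))
      if (!fit$converged || any(!is.finite(fit$coefficients))) stop("nc")
      fit$coefficients[-1]
    }, error = function(e) {
      fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                            lambda = 1e-3)
      message("plain logistic fit failed; using ridge-stabilised coefficients")
      drop(as.matrix(fit$beta))
    })
    names(co) <- support
    co
  }
  list(exposure_coefficients = fit_support(t_obs, exp_sup),
       outcome_coefficients = fit_support(outcome_labels, out_sup))
}

#' Simulate one plasmode replicate
#'
#' Draws \code{n_resample} covariate rows i.i.d. with replacement from the
#' base cohort, then simulates treatment
#' \eqn{T_i \sim Bern(expit(\alpha_0 + w_T^\top x_i))} with \eqn{\alpha_0}
#' calibrated to the target exposure prevalence, and outcome
#' \eqn{Y_i \sim Bern(expit(\gamma_0 + \beta_t T_i + w_Y^\top x_i))} with
#' \eqn{\gamma_0} calibrated, conditional on the realised treatment vector,
#' so the marginal outcome risk matches its target. The replicate seed is a
#' deterministic function of (master seed, replicate index).
#'
#' @param base A \code{base_cohort} (or any object with a \code{covariates}
#'   binary matrix).
#' @param roles A \code{role_assignment} (kept for provenance in the output).
#' @param spec A \code{plasmode_spec}.
#' @param replicate_index Positive integer.
#' @return Object of class \code{plasmode_replicate}: list with
#'   \code{covariates}, \code{treatment}, \code{outcome}, \code{true_beta_t},
#'   \code{replicate_seed}, \code{roles}.
#' @export
simulate_replicate <- function(base, roles, spec, replicate_index = 1L) {
  if (spec$n_resample <= 0L) stop_config("n_resample must be positive")
  x_base <- if (inherits(base, "base_cohort")) base$covariates else base
  nm <- colnames(x_base)
  w_t <- named_into(spec$exposure_coefficients, nm)
  w_y <- named_into(spec$outcome_coefficients, nm)
  rs <- derive_seed(spec$seed, "replicate", replicate_index)
  set.seed(rs)
  rows <- sample.int(nrow(x_base), spec$n_resample, replace = TRUE)
  x <- x_base[rows, , drop = FALSE]
  lp_t <- drop(x %*% w_t)
  a0 <- calibrate_intercept(lp_t, spec$target_exposure_prevalence)
  trt <- as.integer(stats::runif(spec$n_resample) < expit(a0 + lp_t))
  lp_y <- spec$true_beta_t * trt + drop(x %*% w_y)
  g0 <- calibrate_intercept(lp_y, spec$target_outcome_risk)
  y <- as.integer(stats::runif(spec$n_resample) < expit(g0 + lp_y))
  out <- list(covariates = x, treatment = trt, outcome = y,
              true_beta_t = spec$true_beta_t, replicate_seed = rs,
              roles = roles)
  class(out) <- "plasmode_replicate"
  out
}

# expand a named coefficient vector into the full covariate order,
# zero-filled outside its support
named_into <- function(coefs, covariate_names) {
  w <- numeric(length(covariate_names))
  names(w) <- covariate_names
  if (length(coefs)) {
    unknown <- setdiff(names(coefs), covariate_names)
    if (length(unknown)) {
      stop_config("coefficient names not in covariates: %s",
                  paste(utils::head(unknown, 3), collapse = ", "))
    }
    w[names(coefs)] <- coefs
  }
  w
}

#' Run a batch of plasmode replicates
#'
#' Applies \code{\link{simulate_replicate}} for indices 1..n_replicates,
#' either returning the replicates or streaming each one through
#' \code{callback} (to avoid holding all replicates in memory).
#'
#' @param base,roles,spec As in \code{\link{simulate_replicate}}.
#' @param callback Optional \code{function(replicate, index)}; when supplied
#'   its return values are collected in a list instead of the replicates.
#' @return List of replicates, or of callback results.
#' @export
run_plasmode <- function(base, roles, spec, callback = NULL) {
  lapply(seq_len(spec$n_replicates), function(k) {
    rep_k <- simulate_replicate(base, roles, spec, k)
    if (is.null(callback)) rep_k else callback(rep_k, k)
  })
}

#' Write one plasmode replicate to CSV
#'
#' @param replicate A \code{plasmode_replicate}.
#' @param path Output CSV path (row id, T, Y, covariate columns).
#' @return Invisibly, \code{path}.
#' @export
write_replicate <- function(replicate, path) {
  df <- data.frame(row_id = seq_along(replicate$treatment),
                   T = replicate$treatment, Y = replicate$outcome,
                   replicate$covariates, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
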