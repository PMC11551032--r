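# Synthetic base cohort: sparse correlated binary covariates, covariate-driven
# prescriptions, and negative-control time-to-event outcomes whose true hazard
# ratio with respect to treatment is exactly 1 by construction.

#' Configuration for the synthetic base cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults mirror the
#' scale of a UK primary-care antihypertensive cohort: exposure prevalence
#' about 0.26, 69 negative-control outcomes, sparse binary covariates.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param n_covariates Number of binary baseline covariates.
#' @param prevalence_range Length-2 numeric, (low, high) bounds for the
#'   per-covariate marginal prevalences; 0 < low <= high < 1. Prevalences are
#'   drawn log-uniformly inside the range, mimicking the long tail of rare
#'   comorbidity codes.
#' @param latent_correlation Real in [0, 1): pairwise correlation of the
#'   latent Gaussian variables behind the binary covariates (single-factor
#'   model). 0 gives independent covariates.
#' @param study_start_day Integer day offset of study start (day 0).
#' @param study_end_day Integer day offset of study end (exclusive).
#' @param target_exposure_prevalence Probability that a subject ever initiates
#'   treatment; default 0.26.
#' @param n_nco Number of negative-control outcomes; default 69.
#' @param nco_baseline_hazard Baseline hazard (events per day) of the
#'   negative-control exponential event-time model.
#' @param seed Integer seed; same config + seed reproduce the cohort exactly.
#' @return An object of class \code{cohort_config} (a validated list).
#' @export
cohort_config <- function(n_subjects = 20000L,
                          n_covariates = 100L,
                          prevalence_range = c(0.004, 0.30),
                          latent_correlation = 0.2,
                          study_start_day = 0L,
                          study_end_day = 1825L,
                          target_exposure_prevalence = 0.26,
                          n_nco = 69L,
                          nco_baseline_hazard = 2e-5,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_covariates = as.integer(n_covariates),
              prevalence_range = as.numeric(prevalence_range),
              latent_correlation = as.numeric(latent_correlation),
              study_start_day = as.integer(study_start_day),
              study_end_day = as.integer(study_end_day),
              target_exposure_prevalence = as.numeric(target_exposure_prevalence),
              n_nco = as.integer(n_nco),
              nco_baseline_hazard = as.numeric(nco_baseline_hazard),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects <= 0L) stop_config("n_subjects must be positive")
  if (cfg$n_covariates <= 0L) stop_config("n_covariates must be positive")
  pr <- cfg$prevalence_range
  if (length(pr) != 2L || !(pr[1] > 0 && pr[1] <= pr[2] && pr[2] < 1)) {
    stop_config("prevalence_range must satisfy 0 < low <= high < 1")
  }
  if (cfg$latent_correlation < 0 || cfg$latent_correlation >= 1) {
    stop_config("latent_correlation must lie in [0, 1)")
  }
  if (cfg$study_end_day <= cfg$study_start_day) {
    stop_config("study_end_day must exceed study_start_day")
  }
  if (cfg$target_exposure_prevalence < 0 || cfg$target_exposure_prevalence >= 1) {
    stop_config("target_exposure_prevalence must lie in [0, 1)")
  }
  if (cfg$n_nco < 1L) stop_config("n_nco must be >= 1")
  if (cfg$nco_baseline_hazard < 0) stop_config("nco_baseline_hazard must be >= 0")
  invisible(cfg)
}

#' Generate a sparse correlated binary covariate matrix
#'
#' Covariates arise by thresholding a single-factor latent Gaussian model:
#' \eqn{L_{ij} = \sqrt{\rho} F_i + \sqrt{1-\rho}\, \epsilon_{ij}} with
#' standard-normal factor and noise, and \eqn{X_{ij} = 1} iff
#' \eqn{L_{ij} < \Phi^{-1}(p_j)}. Marginal prevalences therefore equal the
#' requested \eqn{p_j} exactly in expectation, while \eqn{\rho > 0} induces
#' positive dependence across covariates, as comorbidity indicators show.
#'
#' @param config A \code{cohort_config}.
#' @return A list with \code{matrix} (n_subjects x n_covariates, 0/1 integer,
#'   column names \code{cov_001}, ...) and \code{prevalence} (the target
#'   marginal prevalences used).
#' @export
generate_covariates <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  p <- config$n_covariates
  rho <- config$latent_correlation
  set.seed(derive_seed(config$seed, "covariates"))
  pr <- config$prevalence_range
  prev <- exp(stats::runif(p, log(pr[1]), log(pr[2])))
  f <- stats::rnorm(n)
  lat <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
  x <- matrix(0L, n, p)
  thr <- stats::qnorm(prev)
  for (j in seq_len(p)) x[, j] <- as.integer(lat[, j] < thr[j])
  colnames(x) <- sprintf("cov_%03d", seq_len(p))
  list(matrix = x, prevalence = prev)
}

#' Generate prescription records driven by covariates
#'
#' Each subject initiates treatment with probability
#' \code{expit(a + uptake_coefficients \%*\% x)}, the intercept \code{a}
#' calibrated so the expected initiator fraction equals
#' \code{target_exposure_prevalence}. Initiators receive 1 to \code{max_rx}
#' prescriptions of 28-90 days; successive refill gaps are drawn short
#' (continuation, < 90 days) with probability 0.8 and long (re-initiation,
#' >= 90 days) otherwise, so downstream era construction sees both cases.
#'
#' @param covariates Binary covariate matrix (n x p).
#' @param uptake_coefficients Length-p numeric; log-odds effect of each
#'   covariate on treatment uptake.
#' @param config A \code{cohort_config}.
#' @param max_rx Maximum number of prescriptions per initiator (default 4).
#' @return A data.frame with columns \code{subject_id}, \code{start_day},
#'   \code{end_day} (half-open day intervals).
#' @export
generate_prescriptions <- function(covariates, uptake_coefficients, config,
                                   max_rx = 4L) {
  validate_cohort_config(config)
  n <- nrow(covariates)
  if (n == 0L) stop_config("empty cohort: no covariate rows")
  if (length(uptake_coefficients) != ncol(covariates)) {
    stop_config("uptake_coefficients length must equal covariate count")
  }
  target <- config$target_exposure_prevalence
  empty <- data.frame(subject_id = integer(0), start_day = integer(0),
                      end_day = integer(0))
  if (target == 0) return(empty)
  set.seed(derive_seed(config$seed, "prescriptions"))
  lp <- drop(covariates %*% uptake_coefficients)
  a <- calibrate_intercept(lp, target)
  initiates <- stats::runif(n) < expit(a + lp)
  ids <- which(initiates)
  if (length(ids) == 0L) return(empty)

  window <- config$study_end_day - config$study_start_day
  n_rx <- sample.int(max_rx, length(ids), replace = TRUE)
  first_start <- config$study_start_day +
    as.integer(floor(stats::runif(length(ids), 0, 0.7 * window)))
  total <- sum(n_rx)
  grp <- rep(seq_along(ids), n_rx)
  dur <- sample(28:90, total, replace = TRUE)
  gap <- ifelse(stats::runif(total) < 0.8,
                sample(0:89, total, replace = TRUE),
                sample(90:365, total, replace = TRUE))
  # cumulative (duration + gap) of earlier prescriptions within each subject
  step <- dur + gap
  offset <- stats::ave(step, grp,
                       FUN = function(v) c(0, cumsum(v[-length(v)])))
  start <- first_start[grp] + as.integer(offset)
  end <- pmin(start + dur, config$study_end_day)
  keep <- start < config$study_end_day
  out <- data.frame(subject_id = ids[grp[keep]], start_day = start[keep],
                    end_day = end[keep])
  rownames(out) <- NULL
  out
}

#' Generate negative-control event times
#'
#' Event times are exponential with per-subject rate
#' \eqn{h_0 \exp(\beta^\top x)}, administratively censored at each subject's
#' follow-up end. Treatment plays no role anywhere in the model, so the true
#' hazard ratio of treatment on every outcome is exactly 1; covariate effects
#' nonetheless create confounding pressure once treatment uptake depends on
#' the same covariates.
#'
#' @param covariates Binary covariate matrix (n x p).
#' @param config A \code{cohort_config}.
#' @param hazard_coefficients Optional p x n_nco matrix of per-outcome
#'   log-hazard-ratio coefficients. By default each outcome gets 10 nonzero
#'   coefficients of magnitude \code{log(1.5)} with random signs on randomly
#'   chosen covariates.
#' @param followup_end_day Per-subject integer follow-up end; defaults to the
#'   study end for everyone.
#' @return A list with \code{event_day} (n x n_nco integer matrix, NA where
#'   censored), \code{observed} (n x n_nco 0/1 matrix) and
#'   \code{coefficients} (the p x n_nco matrix used).
#' @export
generate_nco_events <- function(covariates, config, hazard_coefficients = NULL,
                                followup_end_day = NULL) {
  validate_cohort_config(config)
  if (config$nco_baseline_hazard < 0) stop_config("negative baseline hazard")
  n <- nrow(covariates)
  p <- ncol(covariates)
  m <- config$n_nco
  set.seed(derive_seed(config$seed, "nco"))
  if (is.null(hazard_coefficients)) {
    hazard_coefficients <- matrix(0, p, m)
    k <- min(10L, p)
    for (j in seq_len(m)) {
      idx <- sample.int(p, k)
      hazard_coefficients[idx, j] <- sample(c(-1, 1), k, TRUE) * log(1.5)
    }
  }
  stopifnot(nrow(hazard_coefficients) == p, ncol(hazard_coefficients) == m)
  if (is.null(followup_end_day)) {
    followup_end_day <- rep(config$study_end_day, n)
  }
  fu <- followup_end_day - config$study_start_day
  event_day <- matrix(NA_integer_, n, m)
  observed <- matrix(0L, n, m)
  h0 <- config$nco_baseline_hazard
  if (h0 > 0) {
    for (j in seq_len(m)) {
      rate <- h0 * exp(drop(covariates %*% hazard_coefficients[, j]))
      t_j <- stats::rexp(n, rate)
      ev <- t_j < fu
      observed[, j] <- as.integer(ev)
      event_day[ev, j] <- config$study_start_day + as.integer(ceiling(t_j[ev]))
    }
  }
  colnames(event_day) <- colnames(observed) <- sprintf("nco_%02d", seq_len(m))
  list(event_day = event_day, observed = observed,
       coefficients = hazard_coefficients)
}

#' Generate a complete synthetic base cohort
#'
#' Composes the covariate, prescription and negative-control generators into
#' one \code{base_cohort} object: the substrate that both study arms (the
#' real-world-like negative-control arm and the plasmode arm) resample and
#' analyse.
#'
#' @param config A \code{cohort_config}.
#' @param uptake_coefficients Optional length-p treatment-uptake log-odds
#'   vector; by default 20 randomly chosen covariates get coefficient
#'   \code{log(1.5)} (positive: sicker subjects initiate more).
#' @param nco_hazard_coefficients Optional p x n_nco coefficient matrix
#'   passed to \code{\link{generate_nco_events}}.
#' @return An object of class \code{base_cohort}: a list with
#'   \code{subject_ids}, \code{covariates}, \code{covariate_names},
#'   \code{prescriptions}, \code{followup_end_day}, \code{nco_event_day},
#'   \code{nco_observed}, \code{config} and the generating coefficients.
#' @export
generate_base_cohort <- function(config, uptake_coefficients = NULL,
                                 nco_hazard_coefficients = NULL) {
  validate_cohort_config(config)
  cov <- generate_covariates(config)
  p <- config$n_covariates
  if (is.null(uptake_coefficients)) {
    set.seed(derive_seed(config$seed, "uptake_coef"))
    uptake_coefficients <- numeric(p)
    idx <- sample.int(p, min(20L, p))
    uptake_coefficients[idx] <- log(1.5)
  }
  rx <- generate_prescriptions(cov$matrix, uptake_coefficients, config)
  followup <- rep(config$study_end_day, config$n_subjects)
  nco <- generate_nco_events(cov$matrix, config, nco_hazard_coefficients,
                             followup)
  # one extra covariate-driven (treatment-independent) event series playing
  # the clinical reference outcome: it informs confounder selection and the
  # DRS outcome model, and is never analysed as a negative control
  clin_cfg <- config
  clin_cfg$n_nco <- 1L
  clin_cfg$seed <- derive_seed(config$seed, "clinical_outcome")
  clin <- generate_nco_events(cov$matrix, clin_cfg,
                              followup_end_day = followup)
  out <- list(subject_ids = seq_len(config$n_subjects),
              covariates = cov$matrix,
              covariate_names = colnames(cov$matrix),
              covariate_prevalence = cov$prevalence,
              prescriptions = rx,
              followup_end_day = followup,
              nco_event_day = nco$event_day,
              nco_observed = nco$observed,
              clinical_observed = drop(clin$observed),
              clinical_coefficients = drop(clin$coefficients),
              uptake_coefficients = uptake_coefficients,
              nco_coefficients = nco$coefficients,
              config = config)
  class(out) <- "base_cohort"
  out
}

#' @export
print.base_cohort <- function(x, ...) {
  cat(sprintf(
    "<base_cohort> %d subjects, %d covariates, %d prescription rows, %d NCOs\n",
    length(x$subject_ids), ncol(x$covariates), nrow(x$prescriptions),
    ncol(x$nco_event_day)))
  invisible(x)
}

#' Write a base cohort to CSV files
#'
#' Writes \code{cohort_covariates.csv} (subject_id + one column per
#' covariate), \code{prescriptions.csv} (subject_id, start_day, end_day) and
#' \code{nco_events.csv} (subject_id, outcome_id, event_day, observed_flag;
#' one row per subject-outcome pair with an event). UTF-8, header rows,
#' RFC-4180 quoting.
#'
#' @param cohort A \code{base_cohort}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_base_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  covp <- file.path(dir, "cohort_covariates.csv")
  rxp <- file.path(dir, "prescriptions.csv")
  ncop <- file.path(dir, "nco_events.csv")
  covdf <- data.frame(subject_id = cohort$subject_ids, cohort$covariates,
                      check.names = FALSE)
  utils::write.csv(covdf, covp, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$prescriptions, rxp, row.names = FALSE, quote = FALSE)
  ev <- which(cohort$nco_observed == 1L, arr.ind = TRUE)
  ncodf <- data.frame(subject_id = cohort$subject_ids[ev[, 1]],
                      outcome_id = colnames(cohort$nco_event_day)[ev[, 2]],
                      event_day = cohort$nco_event_day[ev],
                      observed_flag = 1L)
  ncodf <- ncodf[order(ncodf$subject_id, ncodf$outcome_id), , drop = FALSE]
  utils::write.csv(ncodf, ncop, row.names = FALSE, quote = FALSE)
  invisible(c(covp, rxp, ncop))
}

#' Read base-cohort CSV files
#'
#' Counterpart of \code{\link{write_base_cohort}}: reads the three CSVs back
#' into plain data.frames.
#'
#' @param dir Directory containing the files.
#' @return List with \code{covariates}, \code{prescriptions}, \code{nco_events}.
#' @export
read_base_cohort_csvs <- function(dir) {
  list(covariates = utils::read.csv(file.path(dir, "cohort_covariates.csv"),
                                    check.names = FALSE),
       prescriptions = utils::read.csv(file.path(dir, "prescriptions.csv")),
       nco_events = utils::read.csv(file.path(dir, "nco_events.csv")))
}
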