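# Config-driven orchestration of the two study arms over the
# methods x {PS, DRS} grid: the real-world-like arm (synthetic cohort ->
# drug eras -> scores -> matching -> negative-control Cox -> coverage/RMSE)
# and the plasmode arm (roles -> replicates -> scores -> matching ->
# logistic -> relative bias).

#' Experiment configuration
#'
#' Assembles and validates every setting of a full two-arm experiment. Each
#' nested piece is validated by its own constructor; a single
#' \code{master_seed} is fanned out deterministically to every stage.
#'
#' @param cohort A \code{cohort_config} (or a list of its arguments).
#' @param plasmode List of plasmode settings: \code{n_resample},
#'   \code{n_replicates}, \code{true_beta_t},
#'   \code{target_exposure_prevalence}, \code{target_outcome_risk},
#'   \code{role_sizes} (default c(50, 20, 20)), \code{role_strategy}.
#' @param methods Subset of \code{c("reference", "lasso", "xgboost", "mlp")}.
#' @param targets Subset of \code{c("ps", "drs_full", "drs_unexposed")}.
#' @param match A \code{match_config} (or a list of its arguments).
#' @param arms Subset of \code{c("real_world", "plasmode")}.
#' @param confounder_names Optional character vector: the clinically informed
#'   confounder list for the real-world reference method. Defaults to the
#'   covariates with nonzero generating coefficients on treatment uptake or
#'   on the clinical reference outcome.
#' @param hyper_grids Optional named list (per method) of hyperparameter
#'   grids overriding the defaults.
#' @param cv_folds Cross-validation folds for tuning; default 10.
#' @param output_dir Directory for all artifacts.
#' @param master_seed Integer master seed.
#' @return Object of class \code{experiment_config}.
#' @export
experiment_config <- function(cohort = list(), plasmode = list(),
                              methods = "reference", targets = "ps",
                              match = list(), arms = c("real_world", "plasmode"),
                              confounder_names = NULL, hyper_grids = NULL,
                              cv_folds = 10L, output_dir = tempfile("psdrsim_"),
                              master_seed = 1L) {
  errs <- character(0)
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))

  known_m <- c("reference", "lasso", "xgboost", "mlp")
  known_t <- c("ps", "drs_full", "drs_unexposed")
  if (length(methods) == 0L) note("methods: at least one method required")
  bad <- setdiff(methods, known_m)
  if (length(bad)) note("methods: unknown method '%s'", bad[1])
  if (length(targets) == 0L) note("targets: at least one target required")
  bad <- setdiff(targets, known_t)
  if (length(bad)) note("targets: unknown target '%s'", bad[1])
  bad <- setdiff(arms, c("real_world", "plasmode"))
  if (length(bad)) note("arms: unknown arm '%s'", bad[1])

  cohort_cfg <- tryCatch(
    if (inherits(cohort, "cohort_config")) cohort else
      do.call(cohort_config, cohort),
    error = function(e) { note("cohort: %s", conditionMessage(e)); NULL })
  match_cfg <- tryCatch(
    if (inherits(match, "match_config")) match else do.call(match_config, match),
    error = function(e) { note("match: %s", conditionMessage(e)); NULL })

  pl <- utils::modifyList(list(n_resample = 5000L, n_replicates = 100L,
                               true_beta_t = log(2),
                               target_exposure_prevalence = 0.26,
                               target_outcome_risk = 0.0075,
                               role_sizes = c(50L, 20L, 20L),
                               role_strategy = "association"), plasmode)
  if (pl$n_resample < 1L) note("plasmode.n_resample: must be positive")
  if (pl$n_replicates < 1L) note("plasmode.n_replicates: must be positive")
  if (pl$target_outcome_risk <= 0 || pl$target_outcome_risk >= 1) {
    note("plasmode.target_outcome_risk: must lie in (0, 1)")
  }
  if ("plasmode" %in% arms && !is.null(cohort_cfg) &&
      sum(pl$role_sizes) > cohort_cfg$n_covariates) {
    note("plasmode.role_sizes: total %d exceeds n_covariates %d",
         sum(pl$role_sizes), cohort_cfg$n_covariates)
  }
  if (cv_folds < 2L) note("cv_folds: must be >= 2")

  if (length(errs)) {
    stop_config("invalid experiment configuration:\n  - %s",
                paste(errs, collapse = "\n  - "))
  }
  out <- list(cohort = cohort_cfg, plasmode = pl, methods = methods,
              targets = targets, match = match_cfg, arms = arms,
              confounder_names = confounder_names, hyper_grids = hyper_grids,
              cv_folds = as.integer(cv_folds), output_dir = output_dir,
              master_seed = as.integer(master_seed))
  class(out) <- "experiment_config"
  out
}

#' Validate a raw configuration file
#'
#' Reads a YAML or JSON experiment configuration, fills defaults and
#' validates every invariant before any computation; an invalid file stops
#' with every violation listed with the path of the offending field.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{experiment_config}.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- tryCatch({
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }, error = function(e) {
    stop_config("cannot parse config file %s: %s", path, conditionMessage(e))
  })
  if (!is.list(raw)) stop_config("config file must contain a mapping/object")
  allowed <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop_config("unknown configuration field(s): %s",
                paste(unknown, collapse = ", "))
  }
  do.call(experiment_config, raw)
}

score_config_for <- function(method, target, confounder_names, config) {
  grid <- config$hyper_grids[[method]] %||% NULL
  score_model_config(method = method, target = target,
                     confounder_names = if (method == "reference")
                       confounder_names else NULL,
                     hyper_grid = grid, cv_folds = config$cv_folds,
                     seed = derive_seed(config$master_seed,
                                        paste("score", method, target)))
}

#' Run the real-world-like negative-control arm for one method/target cell
#'
#' Fits the score model on the full cohort, matches, computes balance, then
#' fits one Cox model per negative-control outcome on the matched sample and
#' aggregates coverage and RMSE.
#'
#' @param base A \code{base_cohort}.
#' @param cohort data.frame from \code{\link{assign_exposure}}.
#' @param covariates Filtered covariate matrix.
#' @param method,target Cell labels.
#' @param config An \code{experiment_config}.
#' @param confounder_names Reference-method confounder list.
#' @return List with \code{scores}, \code{match}, \code{balance},
#'   \code{estimates}, \code{coverage}, \code{rmse}.
#' @export
run_real_world_cell <- function(base, cohort, covariates, method, target,
                                config, confounder_names) {
  data <- list(covariates = covariates, treatment = cohort$treated,
               outcome = base$clinical_observed)
  sc_cfg <- score_config_for(method, target, confounder_names, config)
  fitted <- fit_score_model(data, sc_cfg)
  match <- greedy_match(fitted$scores, cohort$treated, config$match)
  bal <- balance_report(covariates, cohort$treated, match)
  aset <- matched_analysis_set(match, cohort$index_day)
  estimates <- lapply(seq_len(ncol(base$nco_event_day)), function(j) {
    estimate_hr(aset, base$nco_event_day[, j], cohort$followup_end_day,
                outcome_id = colnames(base$nco_event_day)[j])
  })
  list(scores = fitted, match = match, balance = bal, estimates = estimates,
       coverage = nco_coverage(estimates), rmse = nco_rmse(estimates))
}

#' Run the plasmode arm for one method/target cell
#'
#' For each replicate: fit the score model, match, estimate the matched
#' logistic treatment coefficient and the post-matching ASMD; then summarise
#' relative bias across replicates.
#'
#' @param covariates Filtered base covariate matrix (resampling substrate).
#' @param roles A \code{role_assignment}.
#' @param spec A \code{plasmode_spec}.
#' @param method,target Cell labels.
#' @param config An \code{experiment_config}.
#' @return List with \code{summary} (a \code{simulation_summary}),
#'   \code{beta_hats}, \code{asmd_after}.
#' @export
run_plasmode_cell <- function(covariates, roles, spec, method, target,
                              config) {
  sc_cfg <- score_config_for(method, target, roles$confounders, config)
  beta_hats <- rep(NA_real_, spec$n_replicates)
  asmd_after <- rep(NA_real_, spec$n_replicates)
  asmd_before <- rep(NA_real_, spec$n_replicates)
  for (k in seq_len(spec$n_replicates)) {
    rep_k <- simulate_replicate(covariates, roles, spec, k)
    fitted <- fit_score_model(rep_k, sc_cfg)
    match <- greedy_match(fitted$scores, rep_k$treatment, config$match)
    if (nrow(match$pairs) == 0L) next
    bal <- balance_report(rep_k$covariates, rep_k$treatment, match)
    rows <- c(unique(match$pairs$treated), match$pairs$control)
    eff <- estimate_logor(rep_k$treatment[rows], rep_k$outcome[rows])
    if (eff$estimable) beta_hats[k] <- eff$coef
    asmd_after[k] <- bal$asmd_after
    asmd_before[k] <- bal$asmd_before
  }
  list(summary = summarize_replicates(beta_hats, spec$true_beta_t,
                                      asmd_after, method, target),
       beta_hats = beta_hats, asmd_after = asmd_after,
       asmd_before = asmd_before)
}

#' Run a full two-arm experiment
#'
#' Generates the synthetic base cohort, builds drug eras and exposure
#' status, applies the covariate prevalence filter, then runs every
#' requested (method, target) cell in both arms. A failing cell is recorded
#' with its error message and never interrupts the others. All artifacts are
#' written under \code{config$output_dir}; re-running with the same
#' configuration reproduces every numeric output.
#'
#' @param config An \code{experiment_config}.
#' @return List with \code{base}, \code{cohort}, \code{roles},
#'   \code{cells} (per method/target results), \code{config_echo}; also
#'   written out via \code{\link{render_reports}}.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg_cohort <- config$cohort
  cfg_cohort$seed <- derive_seed(config$master_seed, "cohort")
  base <- generate_base_cohort(cfg_cohort)
  eras <- build_eras(base$prescriptions)
  cohort <- assign_exposure(eras, base)
  filt <- filter_covariates(base$covariates)
  covariates <- filt$matrix

  confounder_names <- config$confounder_names
  if (is.null(confounder_names)) {
    truth <- union(base$covariate_names[base$uptake_coefficients != 0],
                   base$covariate_names[base$clinical_coefficients != 0])
    confounder_names <- intersect(truth, filt$kept)
  }

  roles <- NULL; spec <- NULL
  if ("plasmode" %in% config$arms) {
    pl <- config$plasmode
    roles <- select_covariate_roles(covariates, cohort$treated,
                                    base$clinical_observed,
                                    sizes = pl$role_sizes,
                                    seed = derive_seed(config$master_seed,
                                                       "roles"),
                                    strategy = pl$role_strategy)
    pseudo_base <- list(covariates = covariates,
                        subject_ids = base$subject_ids,
                        clinical_observed = base$clinical_observed)
    coefs <- derive_coefficients(pseudo_base, cohort, roles)
    spec <- plasmode_spec(
      n_resample = pl$n_resample, n_replicates = pl$n_replicates,
      true_beta_t = pl$true_beta_t,
      target_exposure_prevalence = pl$target_exposure_prevalence,
      target_outcome_risk = pl$target_outcome_risk,
      exposure_coefficients = coefs$exposure_coefficients,
      outcome_coefficients = coefs$outcome_coefficients,
      seed = derive_seed(config$master_seed, "plasmode"))
  }

  cells <- list()
  for (method in config$methods) {
    for (target in config$targets) {
      lbl <- sprintf("%s_%s", method, target)
      cell <- list(method = method, target = target)
      if ("real_world" %in% config$arms) {
        rw <- tryCatch(
          run_real_world_cell(base, cohort, covariates, method, target,
                              config, confounder_names),
          error = function(e) conditionMessage(e))
        if (is.character(rw)) {
          cell$error <- rw
        } else {
          cell$nco <- list(estimates = rw$estimates, coverage = rw$coverage,
                           rmse = rw$rmse)
          cell$balance <- rw$balance
          cell$match <- rw$match
        }
      }
      if ("plasmode" %in% config$arms && is.null(cell$error)) {
        pm <- tryCatch(
          run_plasmode_cell(covariates, roles, spec, method, target, config),
          error = function(e) conditionMessage(e))
        if (is.character(pm)) {
          cell$error <- pm
        } else {
          cell$plasmode <- pm$summary
          cell$plasmode_detail <- pm
        }
      }
      cells[[lbl]] <- cell
    }
  }

  results <- list(base = base, cohort = cohort, roles = roles,
                  cells = cells,
                  config_echo = list(master_seed = config$master_seed,
                                     methods = config$methods,
                                     targets = config$targets,
                                     arms = config$arms,
                                     n_subjects = config$cohort$n_subjects,
                                     n_replicates = config$plasmode$n_replicates))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  render_reports(results, config$output_dir)
  results
}
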