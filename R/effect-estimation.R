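# Treatment-effect estimation on matched samples: Cox hazard ratios for
# time-to-event (negative-control) outcomes and logistic log-odds ratios for
# the plasmode binary outcome. Both estimate the ATT: only matched treated
# subjects and their controls enter.

new_effect_estimate <- function(scale, coef, se, n_events,
                                outcome_id = "plasmode", estimable = TRUE) {
  out <- list(scale = scale, coef = coef, se = se,
              ci_low = coef - 1.96 * se, ci_high = coef + 1.96 * se,
              n_events = n_events, outcome_id = outcome_id,
              estimable = estimable)
  class(out) <- "effect_estimate"
  out
}

non_estimable <- function(scale, outcome_id, n_events = 0L) {
  out <- list(scale = scale, coef = NA_real_, se = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, n_events = n_events,
              outcome_id = outcome_id, estimable = FALSE)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<effect_estimate> %s [%s]: non-estimable (%d events)\n",
                x$scale, x$outcome_id, x$n_events))
  } else {
    cat(sprintf("<effect_estimate> %s [%s]: %.4f (%.4f, %.4f), %d events\n",
                x$scale, x$outcome_id, x$coef, x$ci_low, x$ci_high,
                x$n_events))
  }
  invisible(x)
}

#' Build the matched analysis sample with inherited index days
#'
#' Expands a \code{match_result} into one analysis row per matched subject:
#' matched treated subjects keep their own index day; each matched control
#' inherits the index day of the treated subject it was matched to
#' (pseudo-index), which anchors follow-up at a comparable time and avoids
#' immortal-time bias.
#'
#' @param match A \code{match_result} (positions refer to the cohort rows).
#' @param index_day Integer vector over all subjects (treated subjects must
#'   have a non-missing value).
#' @return data.frame with \code{subject}, \code{treated}, \code{index_day}.
#' @export
matched_analysis_set <- function(match, index_day) {
  t_match <- unique(match$pairs$treated)
  rbind(data.frame(subject = t_match, treated = 1L,
                   index_day = index_day[t_match]),
        data.frame(subject = match$pairs$control, treated = 0L,
                   index_day = index_day[match$pairs$treated]))
}

#' Cox hazard ratio on a matched sample
#'
#' Fits an unstratified Cox model with treatment as the only covariate
#' (Efron tie handling, Wald 95\% CI) on the matched analysis set. Follow-up
#' runs from each subject's (inherited) index day to the outcome event or
#' administrative censoring; subjects whose event falls on or before the
#' index day, or with no follow-up beyond it, are excluded from the risk
#' set. Outcomes with zero events in either arm return a flagged
#' non-estimable result instead of failing.
#'
#' @param analysis_set data.frame from \code{\link{matched_analysis_set}}.
#' @param event_day Integer vector over all subjects: outcome event day or
#'   NA when censored.
#' @param followup_end_day Integer vector over all subjects.
#' @param outcome_id Identifier recorded in the result.
#' @param stratified Logical; stratify the Cox fit by matched set (default
#'   \code{FALSE}, a plain unadjusted fit).
#' @param robust Logical; robust (sandwich) variance (default \code{FALSE}).
#' @param set_id Matched-set identifier per analysis row; required when
#'   \code{stratified} or \code{robust}.
#' @return An \code{effect_estimate} with \code{scale = "log_hr"}.
#' @export
estimate_hr <- function(analysis_set, event_day, followup_end_day,
                        outcome_id = "nco", stratified = FALSE,
                        robust = FALSE, set_id = NULL) {
  idx <- analysis_set$subject
  ev <- event_day[idx]
  fu <- followup_end_day[idx]
  t0 <- analysis_set$index_day
  status <- as.integer(!is.na(ev) & ev <= fu)
  time <- ifelse(status == 1L, ev - t0, fu - t0)
  keep <- time > 0 # excludes events on/before index and exhausted follow-up
  time <- time[keep]; status <- status[keep]
  trt <- analysis_set$treated[keep]
  n_events <- sum(status)
  if (n_events == 0L || sum(status[trt == 1]) == 0L ||
      sum(status[trt == 0]) == 0L || length(unique(trt)) < 2L) {
    return(non_estimable("log_hr", outcome_id, n_events))
  }
  df <- data.frame(time = time, status = status, trt = trt)
  if ((stratified || robust) && is.null(set_id)) {
    stop_config("set_id is required for stratified or robust fits")
  }
  fit <- tryCatch({
    if (stratified) {
      df$set <- set_id[keep]
      survival::coxph(survival::Surv(time, status) ~ trt +
                        survival::strata(set), data = df, ties = "efron",
                      robust = robust, id = if (robust) df$set else NULL)
    } else if (robust) {
      df$set <- set_id[keep]
      survival::coxph(survival::Surv(time, status) ~ trt, data = df,
                      ties = "efron", robust = TRUE, id = df$set)
    } else {
      survival::coxph(survival::Surv(time, status) ~ trt, data = df,
                      ties = "efron")
    }
  }, error = function(e) NULL, warning = function(w) {
    suppressWarnings(survival::coxph(survival::Surv(time, status) ~ trt,
                                     data = df, ties = "efron"))
  })
  if (is.null(fit) || !is.finite(stats::coef(fit)[["trt"]])) {
    return(non_estimable("log_hr", outcome_id, n_events))
  }
  se <- sqrt(diag(stats::vcov(fit)))[["trt"]]
  new_effect_estimate("log_hr", stats::coef(fit)[["trt"]], se, n_events,
                      outcome_id)
}

#' Logistic log-odds ratio on a matched sample
#'
#' Intercept + treatment logistic regression on the matched plasmode sample;
#' the treatment coefficient is the ATT log-odds ratio with a Wald 95\% CI.
#' Because treatment is the only covariate, the estimate equals the
#' closed-form 2x2-table log-odds ratio exactly.
#'
#' @param treatment Binary vector (matched sample).
#' @param outcome Binary vector (matched sample).
#' @return An \code{effect_estimate} with \code{scale = "log_or"}.
#' @export
estimate_logor <- function(treatment, outcome) {
  if (length(treatment) != length(outcome)) {
    stop_config("treatment and outcome lengths differ")
  }
  tab <- table(factor(treatment, levels = c(0, 1)),
               factor(outcome, levels = c(0, 1)))
  if (any(rowSums(tab) == 0L) || length(unique(outcome)) < 2L) {
    return(non_estimable("log_or", "plasmode", sum(outcome)))
  }
  if (any(tab == 0L)) {
    return(non_estimable("log_or", "plasmode", sum(outcome)))
  }
  fit <- stats::glm(outcome ~ treatment, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 50L))
  co <- summary(fit)$coefficients
  new_effect_estimate("log_or", co["treatment", "Estimate"],
                      co["treatment", "Std. Error"], sum(outcome))
}
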