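# Drug-era construction, user/non-user classification and the covariate
# prevalence filter.

#' Build exposure eras from prescription records
#'
#' Concatenates each subject's prescriptions into continuous treatment eras:
#' within a subject, a prescription whose start falls strictly less than
#' \code{gap_days} after the running era end is merged into that era (the era
#' end extends to the max end seen so far); a gap of \code{gap_days} or more
#' starts a new era. With the default \code{gap_days = 90} this is the
#' standard "< 90-day refill gap" drug-era rule: a gap of 89 days merges, a
#' gap of exactly 90 splits.
#'
#' @param prescriptions data.frame with \code{subject_id}, \code{start_day},
#'   \code{end_day} (half-open intervals, \code{end_day > start_day}).
#' @param gap_days Positive integer refill-gap threshold; default 90.
#' @return data.frame with \code{subject_id}, \code{era_start_day},
#'   \code{era_end_day}, sorted by subject then era start.
#' @export
build_eras <- function(prescriptions, gap_days = 90L) {
  stopifnot(gap_days >= 1L)
  req <- c("subject_id", "start_day", "end_day")
  if (!all(req %in% names(prescriptions))) {
    stop_config("prescriptions must have columns subject_id, start_day, end_day")
  }
  bad <- which(prescriptions$end_day <= prescriptions$start_day)
  if (length(bad)) {
    stop_config("prescription row %d has end_day <= start_day (subject %s)",
                bad[1], prescriptions$subject_id[bad[1]])
  }
  if (nrow(prescriptions) == 0L) {
    return(data.frame(subject_id = integer(0), era_start_day = integer(0),
                      era_end_day = integer(0)))
  }
  o <- order(prescriptions$subject_id, prescriptions$start_day,
             prescriptions$end_day)
  sid <- prescriptions$subject_id[o]
  s <- prescriptions$start_day[o]
  e <- prescriptions$end_day[o]
  n <- length(sid)
  # Single sweep over rows sorted by (subject, start): a new era begins when
  # the subject changes or the gap since the running era end is >= gap_days;
  # the running era end is the max end over the rows merged so far.
  out_sid <- integer(n); out_s <- integer(n); out_e <- integer(n)
  k <- 0L
  cur_sid <- sid[1]; cur_s <- s[1]; cur_e <- e[1]
  if (n > 1L) for (i in 2:n) {
    if (sid[i] == cur_sid && s[i] - cur_e < gap_days) {
      if (e[i] > cur_e) cur_e <- e[i]
    } else {
      k <- k + 1L
      out_sid[k] <- cur_sid; out_s[k] <- cur_s; out_e[k] <- cur_e
      cur_sid <- sid[i]; cur_s <- s[i]; cur_e <- e[i]
    }
  }
  k <- k + 1L
  out_sid[k] <- cur_sid; out_s[k] <- cur_s; out_e[k] <- cur_e
  data.frame(subject_id = out_sid[seq_len(k)], era_start_day = out_s[seq_len(k)],
             era_end_day = out_e[seq_len(k)])
}

#' Classify subjects as users or non-users
#'
#' A subject is a user (treated) iff they have at least one era starting
#' within the study window; the index day is the start of the first such era.
#' Non-users carry no index day here — in matched analyses they inherit a
#' pseudo-index from the treated subject they are matched to, which avoids
#' immortal-time bias.
#'
#' @param eras data.frame from \code{\link{build_eras}}.
#' @param base A \code{base_cohort}.
#' @return data.frame (one row per subject) with \code{subject_id},
#'   \code{treated}, \code{index_day} (NA for non-users),
#'   \code{followup_end_day}.
#' @export
assign_exposure <- function(eras, base) {
  cfg <- base$config
  unknown <- setdiff(unique(eras$subject_id), base$subject_ids)
  if (length(unknown)) {
    stop_config("era refers to unknown subject id(s): %s",
                paste(utils::head(unknown, 3), collapse = ", "))
  }
  in_window <- eras$era_start_day >= cfg$study_start_day &
    eras$era_start_day < cfg$study_end_day
  ew <- eras[in_window, , drop = FALSE]
  first_idx <- tapply(ew$era_start_day, ew$subject_id, min)
  n <- length(base$subject_ids)
  treated <- integer(n)
  index_day <- rep(NA_integer_, n)
  pos <- match(as.integer(names(first_idx)), base$subject_ids)
  treated[pos] <- 1L
  index_day[pos] <- as.integer(first_idx)
  if (all(treated == 1L)) {
    warning("every subject is a user: no non-user comparators available")
  }
  data.frame(subject_id = base$subject_ids, treated = treated,
             index_day = index_day, followup_end_day = base$followup_end_day)
}

#' Filter out low-prevalence covariates
#'
#' Keeps a covariate iff its empirical prevalence strictly exceeds
#' \code{min_prevalence_exclusive}; the conventional cut of 0.004 therefore
#' excludes a covariate whose prevalence is exactly 0.004. Column order is
#' preserved.
#'
#' @param covariates Binary matrix with column names.
#' @param min_prevalence_exclusive Exclusive lower prevalence bound
#'   (default 0.004).
#' @return List with \code{matrix} (filtered) and \code{kept} (names).
#' @export
filter_covariates <- function(covariates, min_prevalence_exclusive = 0.004) {
  if (is.null(dim(covariates)) || nrow(covariates) == 0L ||
      ncol(covariates) == 0L) {
    stop_config("covariate matrix is empty")
  }
  prev <- colMeans(covariates)
  keep <- prev > min_prevalence_exclusive
  list(matrix = covariates[, keep, drop = FALSE],
       kept = colnames(covariates)[keep])
}
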