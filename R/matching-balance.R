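# Greedy variable-ratio caliper matching on a score, and covariate balance
# diagnostics (per-covariate standardised mean differences and their average).

#' Matching configuration
#'
#' @param max_ratio Maximum controls per treated subject (default 5).
#' @param caliper Maximum |score(treated) - score(control)| on the score's
#'   probability scale (default 0.05).
#' @param with_replacement Logical; if \code{FALSE} (default) a control is
#'   used at most once overall, if \code{TRUE} it may serve several treated
#'   subjects (but appears at most once within one matched set).
#' @param seed Integer seed (kept for provenance; the algorithm itself is
#'   deterministic).
#' @return Object of class \code{match_config}.
#' @export
match_config <- function(max_ratio = 5L, caliper = 0.05,
                         with_replacement = FALSE, seed = 1L) {
  if (max_ratio < 1L) stop_config("match.max_ratio must be >= 1")
  if (!is.numeric(caliper) || caliper <= 0) {
    stop_config("match.caliper must be a positive real")
  }
  out <- list(max_ratio = as.integer(max_ratio), caliper = as.numeric(caliper),
              with_replacement = isTRUE(with_replacement),
              seed = as.integer(seed))
  class(out) <- "match_config"
  out
}

#' Greedy variable-ratio caliper matching
#'
#' Deterministic greedy matcher targeting the ATT. The algorithm makes
#' \code{max_ratio} passes; in each pass, treated subjects are processed in a
#' fixed order (descending score, ties by position) and each one still in
#' play is assigned its nearest available control within the caliper, with
#' controls kept in (ascending score, position) order and an exact distance
#' tie resolved toward the lower-score neighbour. A treated subject that
#' finds no control in some pass is finished (it keeps the controls it
#' already has; a subject with none after pass 1 is unmatched). Matching
#' high scores first, one control per pass, prevents early treated subjects
#' from monopolising scarce controls.
#'
#' @param scores Numeric vector of scores in [0, 1] (one per subject).
#' @param treated_flags Binary/logical vector: 1 = treated.
#' @param config A \code{match_config}.
#' @return Object of class \code{match_result}: list with \code{pairs}
#'   (data.frame \code{treated}, \code{control}, \code{pass} — positions into
#'   the input vectors), \code{n_treated_matched},
#'   \code{n_treated_unmatched}, \code{config}.
#' @export
greedy_match <- function(scores, treated_flags, config = match_config()) {
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop_config("scores must be finite probabilities in [0, 1]")
  }
  treated_flags <- as.logical(treated_flags)
  t_idx <- which(treated_flags)
  c_idx <- which(!treated_flags)
  if (length(t_idx) == 0L || length(c_idx) == 0L) {
    stop_config("both a treated and a control group are required")
  }
  pm <- .greedy_match_cpp(as.numeric(scores), treated_flags,
                          config$max_ratio, config$caliper,
                          config$with_replacement)
  pairs_t <- pm[, 1]; pairs_c <- pm[, 2]; pairs_p <- pm[, 3]

  matched <- unique(pairs_t)
  if (length(matched) == 0L) {
    warning("no treated subject could be matched within the caliper")
  }
  out <- list(pairs = data.frame(treated = pairs_t, control = pairs_c,
                                 pass = pairs_p),
              n_treated_matched = length(matched),
              n_treated_unmatched = length(t_idx) - length(matched),
              config = config)
  class(out) <- "match_result"
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d treated matched (%d unmatched), %d pairs\n",
              x$n_treated_matched, x$n_treated_unmatched, nrow(x$pairs)))
  invisible(x)
}

# prevalence-based SMD for binary covariates; 0/0 convention -> 0
smd_from_prev <- function(p1, p0) {
  num <- abs(p1 - p0)
  den <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  ifelse(num == 0, 0, num / den)
}

#' Standardised mean difference for a binary covariate
#'
#' The two-proportion pooled form
#' \eqn{|p_1 - p_0| / \sqrt{(p_1(1-p_1) + p_0(1-p_0))/2}}; defined as 0 when
#' both prevalences are equal, including the degenerate all-zero/all-one
#' case.
#'
#' @param covariate_values_treated Binary vector (treated group).
#' @param covariate_values_control Binary vector (control group).
#' @return Nonnegative scalar.
#' @export
smd <- function(covariate_values_treated, covariate_values_control) {
  if (length(covariate_values_treated) == 0L ||
      length(covariate_values_control) == 0L) {
    stop_config("both groups must be non-empty")
  }
  smd_from_prev(mean(covariate_values_treated), mean(covariate_values_control))
}

#' Covariate balance before and after matching
#'
#' Per-covariate SMDs and their average (ASMD) computed on the full sample
#' (before) and on the matched sample (after: matched treated subjects once
#' each, plus their controls). With variable-ratio sets, the default counts
#' every matched control once, mirroring a plain matched-sample analysis; set
#' \code{weighted = TRUE} to weight each control by 1/k within a 1:k set,
#' which targets the ATT covariate distribution exactly.
#'
#' @param covariates Binary matrix (all subjects).
#' @param treated_flags Binary/logical vector.
#' @param match A \code{match_result} from \code{\link{greedy_match}}.
#' @param weighted Logical; default \code{FALSE}.
#' @return Object of class \code{balance_report}: list with
#'   \code{per_covariate_smd_before}, \code{per_covariate_smd_after},
#'   \code{asmd_before}, \code{asmd_after},
#'   \code{n_covariates_above_0.1_after}.
#' @export
balance_report <- function(covariates, treated_flags, match,
                           weighted = FALSE) {
  treated_flags <- as.logical(treated_flags)
  if (nrow(match$pairs) == 0L) stop_config("matched set is empty")
  p1_before <- colMeans(covariates[treated_flags, , drop = FALSE])
  p0_before <- colMeans(covariates[!treated_flags, , drop = FALSE])
  smd_before <- smd_from_prev(p1_before, p0_before)

  t_match <- unique(match$pairs$treated)
  p1_after <- colMeans(covariates[t_match, , drop = FALSE])
  if (weighted) {
    k_per_t <- table(match$pairs$treated)
    w <- 1 / as.numeric(k_per_t[as.character(match$pairs$treated)])
    cw <- covariates[match$pairs$control, , drop = FALSE] * w
    p0_after <- colSums(cw) / sum(w)
  } else {
    p0_after <- colMeans(covariates[match$pairs$control, , drop = FALSE])
  }
  smd_after <- smd_from_prev(p1_after, p0_after)

  out <- list(per_covariate_smd_before = smd_before,
              per_covariate_smd_after = smd_after,
              asmd_before = mean(smd_before),
              asmd_after = mean(smd_after),
              n_covariates_above_0.1_after = sum(smd_after > 0.1))
  class(out) <- "balance_report"
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> ASMD before %.4f, after %.4f (%d covariates > 0.1 after)\n",
              x$asmd_before, x$asmd_after, x$n_covariates_above_0.1_after))
  invisible(x)
}
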