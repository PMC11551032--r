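#' @keywords internal
#' @useDynLib psdrsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Inverse logit
#'
#' @param x Numeric vector on the log-odds scale.
#' @return Probabilities in (0, 1).
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit
#'
#' @param p Probabilities strictly inside (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

#' Derive a reproducible sub-stream seed
#'
#' Deterministically fans a master seed out into per-stage / per-replicate
#' seeds so that one integer reproduces an entire experiment while distinct
#' stages and replicates get effectively independent streams. The map is a
#' small multiply-xor hash computed in double precision and reduced modulo
#' 2^31 - 1, so the result is always a valid positive R integer.
#'
#' @param master_seed Integer master seed.
#' @param stream Character scalar naming the consumer (e.g. "plasmode").
#' @param index Non-negative integer, e.g. a replicate index. Default 0.
#' @return A positive integer seed, strictly below 2^31.
#' @export
derive_seed <- function(master_seed, stream, index = 0L) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(stream) == 1L, is.character(stream),
            length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(master_seed)) %% m)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 48271 + as.numeric(index) * 16807 + 1) %% m
  as.integer(h %% m) + 1L
}

#' Calibrate an intercept to hit a target mean probability
#'
#' Finds the intercept \eqn{a} such that \code{mean(expit(a + lp))} equals
#' \code{target} by bisection, expanding the bracket until it contains the
#' root. The achieved mean is within \code{tol} of the target; the map
#' \eqn{a \mapsto mean(expit(a + lp))} is strictly increasing so the root is
#' unique.
#'
#' @param linear_predictor Numeric vector of linear predictors (no intercept).
#' @param target_prevalence Target mean probability, strictly in (0, 1).
#' @param tol Convergence tolerance on the achieved mean; default 1e-10.
#' @return The calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(linear_predictor, target_prevalence,
                                tol = 1e-10) {
  stopifnot(is.numeric(linear_predictor), length(linear_predictor) >= 1L,
            all(is.finite(linear_predictor)))
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1) {
    stop("`target_prevalence` must be a probability strictly in (0, 1)")
  }
  f <- function(a) mean(expit(a + linear_predictor)) - target_prevalence
  lo <- logit(target_prevalence) - max(abs(linear_predictor)) - 1
  hi <- logit(target_prevalence) + max(abs(linear_predictor)) + 1
  while (f(lo) > 0) lo <- lo - (hi - lo)
  while (f(hi) < 0) hi <- hi + (hi - lo)
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
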