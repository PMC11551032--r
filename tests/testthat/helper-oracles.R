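# Independent brute-force oracles and small data generators used across the
# suite. These deliberately re-implement the documented rules from scratch
# (linear scans, day-grid enumeration) rather than calling package internals.

# Greedy variable-ratio caliper matching by linear outward scan over the
# (ascending score, position)-sorted control line: pass k = 1..max_ratio;
# treated processed in (descending score, position) order; each still-active
# treated takes its nearest available control within the caliper, preferring
# the lower-score (left) neighbour on an exact distance tie; failure
# deactivates the treated subject.
oracle_greedy_match <- function(scores, treated_flags, max_ratio, caliper,
                                with_replacement = FALSE) {
  treated_flags <- as.logical(treated_flags)
  t_idx <- which(treated_flags)
  c_idx <- which(!treated_flags)
  t_ord <- t_idx[order(-scores[t_idx], t_idx)]
  c_ord <- c_idx[order(scores[c_idx], c_idx)]
  sc <- scores[c_ord]
  m <- length(c_ord)
  avail <- rep(TRUE, m)
  active <- rep(TRUE, length(t_ord))
  own <- lapply(t_ord, function(i) integer(0))
  out <- list()
  for (pass in seq_len(max_ratio)) {
    for (ti in seq_along(t_ord)) {
      if (!active[ti]) next
      s <- scores[t_ord[ti]]
      usable <- if (with_replacement) !(c_ord %in% own[[ti]]) else avail
      l <- max(c(0L, which(sc <= s & usable)))
      r_cands <- which(sc > s & usable)
      r <- if (length(r_cands)) min(r_cands) else 0L
      dl <- if (l >= 1L) s - sc[l] else Inf
      dr <- if (r >= 1L) sc[r] - s else Inf
      if (min(dl, dr) > caliper) { active[ti] <- FALSE; next }
      ppos <- if (dl <= dr) l else r
      pick <- c_ord[ppos]
      if (!with_replacement) avail[ppos] <- FALSE
      own[[ti]] <- c(own[[ti]], pick)
      out[[length(out) + 1L]] <- c(t_ord[ti], pick, pass)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(treated = integer(0), control = integer(0),
                      pass = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(treated = m[, 1], control = m[, 2], pass = m[, 3])
}

# Era construction by day-grid enumeration: mark every day covered by a
# prescription, form coverage blocks, then fuse blocks separated by fewer
# than gap_days uncovered days.
oracle_build_eras <- function(prescriptions, gap_days = 90L) {
  out <- list()
  for (sid in sort(unique(prescriptions$subject_id))) {
    rows <- prescriptions[prescriptions$subject_id == sid, , drop = FALSE]
    days <- sort(unique(unlist(Map(function(a, b) seq(a, b - 1L),
                                   rows$start_day, rows$end_day))))
    brk <- c(0L, which(diff(days) > 1L), length(days))
    blocks <- cbind(days[brk[-length(brk)] + 1L], days[brk[-1L]] + 1L)
    cur <- blocks[1, ]
    for (r in seq_len(nrow(blocks))[-1]) {
      if (blocks[r, 1] - cur[2] < gap_days) {
        cur[2] <- blocks[r, 2]
      } else {
        out[[length(out) + 1L]] <- c(sid, cur)
        cur <- blocks[r, ]
      }
    }
    out[[length(out) + 1L]] <- c(sid, cur)
  }
  m <- do.call(rbind, out)
  data.frame(subject_id = m[, 1], era_start_day = m[, 2], era_end_day = m[, 3])
}

# random prescription table for oracle-equivalence sweeps
random_prescriptions <- function(n_subjects, max_rows = 6L,
                                 horizon = 700L) {
  rows <- list()
  for (sid in seq_len(n_subjects)) {
    k <- sample.int(max_rows, 1L)
    start <- sort(sample.int(horizon, k))
    dur <- sample(1:120, k, replace = TRUE)
    rows[[sid]] <- data.frame(subject_id = sid, start_day = start,
                              end_day = start + dur)
  }
  df <- do.call(rbind, rows)
  df[sample.int(nrow(df)), , drop = FALSE] # shuffle row order
}

# small logistic-treatment data set with known coefficient vector
make_ps_data <- function(n, p, beta, intercept = -1, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, sprintf("cov_%03d", seq_len(p))))
  t_vec <- rbinom(n, 1, plogis(intercept + drop(x %*% beta)))
  list(covariates = x, treatment = t_vec,
       true_ps = plogis(intercept + drop(x %*% beta)))
}
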