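# Aggregation of effect estimates into the study metrics: negative-control
# coverage and RMSE, plasmode relative bias with normal-approximation CIs,
# and ASMD summaries across replicates, plus the tables and figures.

#' Relative bias of an estimated coefficient
#'
#' \eqn{(\hat\beta_t - \beta_t) / \beta_t} on the coefficient (log-odds)
#' scale, sign preserved.
#'
#' @param beta_hat Estimated coefficient.
#' @param beta_true True (injected) coefficient; must be nonzero.
#' @return Real scalar.
#' @export
relative_bias <- function(beta_hat, beta_true) {
  if (any(beta_true == 0)) {
    stop_config("beta_true is 0: relative bias undefined; use absolute bias")
  }
  (beta_hat - beta_true) / beta_true
}

estimates_frame <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(outcome_id = e$outcome_id, scale = e$scale, coef = e$coef,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               n_events = e$n_events, estimable = e$estimable)
  }))
}

#' Coverage of the null across negative-control outcomes
#'
#' Fraction of estimable outcomes whose 95\% CI on the log-HR scale contains
#' 0 (i.e., whose HR interval contains 1). The denominator counts estimable
#' outcomes only; the number dropped is reported alongside.
#'
#' @param estimates List of \code{effect_estimate}s (one per outcome).
#' @return List with \code{coverage} (fraction), \code{n_estimable},
#'   \code{n_dropped}.
#' @export
nco_coverage <- function(estimates) {
  df <- estimates_frame(estimates)
  est <- df[df$estimable, , drop = FALSE]
  if (nrow(est) == 0L) stop_config("no estimable negative-control outcome")
  list(coverage = mean(est$ci_low <= 0 & est$ci_high >= 0),
       n_estimable = nrow(est), n_dropped = sum(!df$estimable))
}

#' RMSE of negative-control effect estimates
#'
#' With a true null effect the RMSE reduces to the root mean square of the
#' estimates themselves: \code{sqrt(mean(coef^2))} on the log-HR scale
#' (default), or \code{sqrt(mean((exp(coef) - 1)^2))} on the HR scale.
#' Non-estimable outcomes are excluded.
#'
#' @param estimates List of \code{effect_estimate}s.
#' @param scale_mode \code{"log"} (default) or \code{"hr"}.
#' @return List with \code{rmse}, \code{scale_mode}, \code{n_estimable}.
#' @export
nco_rmse <- function(estimates, scale_mode = c("log", "hr")) {
  scale_mode <- match.arg(scale_mode)
  df <- estimates_frame(estimates)
  est <- df[df$estimable, , drop = FALSE]
  if (nrow(est) == 0L) stop_config("no estimable negative-control outcome")
  rmse <- if (scale_mode == "log") {
    sqrt(mean(est$coef^2))
  } else {
    sqrt(mean((exp(est$coef) - 1)^2))
  }
  list(rmse = rmse, scale_mode = scale_mode, n_estimable = nrow(est))
}

#' Summarise plasmode replicates
#'
#' Mean and normal-approximation 95\% CI (mean +/- 1.96 sd/sqrt(n)) over
#' replicates, for the relative bias of the estimated treatment coefficient
#' and for the post-matching ASMD. Replicates whose effect was non-estimable
#' are dropped and counted.
#'
#' @param beta_hats Numeric vector of per-replicate estimates (NA where
#'   non-estimable).
#' @param beta_true The injected true coefficient.
#' @param asmd_after Numeric vector of per-replicate post-matching ASMDs.
#' @param method,target Labels recorded in the summary.
#' @return Object of class \code{simulation_summary}.
#' @export
summarize_replicates <- function(beta_hats, beta_true, asmd_after = NULL,
                                 method = NA_character_,
                                 target = NA_character_) {
  ok <- is.finite(beta_hats)
  if (sum(ok) < 2L) stop_config("need >= 2 estimable replicates to summarise")
  rb <- relative_bias(beta_hats[ok], beta_true)
  n <- sum(ok)
  half <- 1.96 * stats::sd(rb) / sqrt(n)
  out <- list(method = method, target = target,
              mean_relative_bias = mean(rb),
              rb_ci_low = mean(rb) - half, rb_ci_high = mean(rb) + half,
              n_replicates = n, n_dropped = sum(!ok))
  if (!is.null(asmd_after)) {
    a <- asmd_after[ok]
    ha <- 1.96 * stats::sd(a) / sqrt(n)
    out$mean_asmd_after <- mean(a)
    out$asmd_ci_low <- mean(a) - ha
    out$asmd_ci_high <- mean(a) + ha
  }
  class(out) <- "simulation_summary"
  out
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("<simulation_summary> %s/%s: relative bias %.4f (%.4f, %.4f), n=%d\n",
              x$method, x$target, x$mean_relative_bias, x$rb_ci_low,
              x$rb_ci_high, x$n_replicates))
  invisible(x)
}

#' Write evaluation tables and figures
#'
#' Renders the standard report artifacts from a set of per-cell results:
#' \code{nco_coverage.csv} (per method/target coverage, RMSE), paired
#' PS-vs-DRS summary columns where both targets are present,
#' \code{summary_ps.csv} / \code{summary_drs.csv} for plasmode summaries, a
#' before/after ASMD scatter with the 0.1 balance threshold line, a
#' per-outcome forest-style coverage plot coloured by two-sided 0.05
#' significance, and \code{report.json} aggregating every metric. Missing
#' inputs are skipped with a warning rather than failing the report.
#'
#' @param results List as assembled by \code{\link{run_experiment}}: per
#'   (method, target) cells with elements \code{nco} (estimates, coverage,
#'   rmse), \code{balance} and \code{plasmode} (a
#'   \code{simulation_summary}).
#' @param dir Output directory.
#' @return Invisibly, the path of \code{report.json}.
#' @export
render_reports <- function(results, dir) {
  dir.create(file.path(dir, "figures"), showWarnings = FALSE, recursive = TRUE)
  rows_nco <- list(); rows_sim <- list()
  for (cell in results$cells) {
    lbl <- sprintf("%s_%s", cell$method, cell$target)
    if (!is.null(cell$error)) {
      warning(sprintf("cell %s failed: %s; skipped in report", lbl,
                      cell$error))
      next
    }
    if (!is.null(cell$nco)) {
      rows_nco[[lbl]] <- data.frame(
        method = cell$method, target = cell$target,
        coverage_pct = 100 * cell$nco$coverage$coverage,
        rmse = cell$nco$rmse$rmse,
        n_estimable = cell$nco$coverage$n_estimable,
        asmd_before = cell$balance$asmd_before,
        asmd_after = cell$balance$asmd_after)
      df <- estimates_frame(cell$nco$estimates)
      utils::write.csv(df, file.path(dir, sprintf("effects_nco_%s.csv", lbl)),
                       row.names = FALSE)
      est <- df[df$estimable, , drop = FALSE]
      if (nrow(est)) {
        est$significant <- est$ci_low > 0 | est$ci_high < 0
        est$ord <- seq_len(nrow(est))
        gg <- ggplot2::ggplot(est, ggplot2::aes(x = exp(coef), y = ord,
                                                colour = significant)) +
          ggplot2::geom_point() +
          ggplot2::geom_errorbarh(ggplot2::aes(xmin = exp(ci_low),
                                               xmax = exp(ci_high)),
                                  height = 0) +
          ggplot2::geom_vline(xintercept = 1, linetype = 2) +
          ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                                  `TRUE` = "darkorange")) +
          ggplot2::scale_x_log10() +
          ggplot2::labs(x = "Hazard ratio (95% CI)", y = "Negative-control outcome",
                        title = sprintf("Negative-control coverage: %s", lbl))
        ggplot2::ggsave(file.path(dir, "figures",
                                  sprintf("nco_coverage_%s.png", lbl)),
                        gg, width = 7, height = 6, dpi = 120)
      }
    }
    if (!is.null(cell$balance)) {
      bal <- data.frame(covariate = names(cell$balance$per_covariate_smd_before),
                        smd_before = cell$balance$per_covariate_smd_before,
                        smd_after = cell$balance$per_covariate_smd_after)
      utils::write.csv(bal, file.path(dir, sprintf("balance_%s.csv", lbl)),
                       row.names = FALSE)
      gg <- ggplot2::ggplot(bal, ggplot2::aes(x = smd_before, y = smd_after)) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::geom_hline(yintercept = 0.1, linetype = 2) +
        ggplot2::labs(x = "SMD before matching", y = "SMD after matching",
                      title = sprintf("Covariate balance: %s", lbl))
      ggplot2::ggsave(file.path(dir, "figures", sprintf("asmd_%s.png", lbl)),
                      gg, width = 6, height = 6, dpi = 120)
    }
    if (!is.null(cell$plasmode)) {
      s <- cell$plasmode
      rows_sim[[lbl]] <- data.frame(
        method = s$method, target = s$target,
        mean_relative_bias = s$mean_relative_bias,
        rb_ci_low = s$rb_ci_low, rb_ci_high = s$rb_ci_high,
        mean_asmd_after = s$mean_asmd_after %||% NA_real_,
        n_replicates = s$n_replicates)
    }
  }
  if (length(rows_nco)) {
    nco_tab <- do.call(rbind, rows_nco)
    # juxtapose PS and DRS columns per method when both targets are present
    if (all(c("ps") %in% nco_tab$target) && any(grepl("^drs", nco_tab$target))) {
      ps <- nco_tab[nco_tab$target == "ps", ]
      drs <- nco_tab[grepl("^drs", nco_tab$target), ]
      cmp <- merge(drs[, c("method", "coverage_pct", "rmse")],
                   ps[, c("method", "coverage_pct", "rmse")],
                   by = "method", suffixes = c("_drs", "_ps"))
      names(cmp) <- c("method", "coverage_drs_pct", "rmse_drs",
                      "coverage_ps_pct", "rmse_ps")
      utils::write.csv(cmp, file.path(dir, "nco_ps_vs_drs.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(nco_tab, file.path(dir, "nco_coverage.csv"),
                     row.names = FALSE)
  } else {
    warning("no negative-control results: coverage table and plot skipped")
  }
  if (length(rows_sim)) {
    sim_tab <- do.call(rbind, rows_sim)
    utils::write.csv(sim_tab[sim_tab$target == "ps", , drop = FALSE],
                     file.path(dir, "summary_ps.csv"), row.names = FALSE)
    utils::write.csv(sim_tab[grepl("^drs", sim_tab$target), , drop = FALSE],
                     file.path(dir, "summary_drs.csv"), row.names = FALSE)
  }
  report <- list(
    config = results$config_echo,
    nco = if (length(rows_nco)) do.call(rbind, rows_nco) else NULL,
    plasmode = if (length(rows_sim)) do.call(rbind, rows_sim) else NULL)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
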