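#' Replicate virtual trials and aggregate operating characteristics
#'
#' Runs `n_replicates` independent virtual trials, analyzes each with
#' [analyze_trial()], and aggregates: means of events (by mode), exposure
#' and mammogram counts; hazards recomputed from mean events over mean
#' exposure; and, for every risk difference, the across-replicate mean, the
#' 2.5th/97.5th percentile interval, and P(R < 0) — the fraction of
#' replicates in which the risk difference is strictly below zero
#' (replicates with R exactly 0 count toward neither side and are reported
#' separately).
#'
#' One master seed spawns a per-replicate seed stream, so results are
#' reproducible and prefix-stable: replicates 1..k are identical whatever
#' `n_replicates >= k` is.
#'
#' @param config a `trial_config`.
#' @param n_replicates number of virtual trials (>= 1).
#' @param seed master seed (falls back to `config$seed`, then to 1).
#' @param methods analysis methods, passed to [analyze_trial()].
#' @param keep_replicates keep the per-replicate risk-difference matrix.
#' @param progress print a progress message every `progress` replicates
#'   (0 = quiet).
#' @return an object of class `aggregate_result` with `summary`, `risk`,
#'   `replicate_events` (total detected per replicate), and optionally
#'   `replicate_risk`.
#' @export
run_experiment <- function(config, n_replicates, seed = NULL,
                           methods = c("total_time", "complete_cycles",
                                       "complete_cycles_entry_mammo",
                                       "hybrid"),
                           keep_replicates = FALSE, progress = 0) {
  stopifnot(n_replicates >= 1)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)

  sum_cols <- c("n_women", "n_included", "n_prevalent", "events",
                "events_screen", "events_clinical", "events_prevalent",
                "exposure", "n_mammograms")
  summary_acc <- NULL
  risk_mat <- NULL
  risk_key <- NULL
  events_total <- numeric(n_replicates)

  for (i in seq_len(n_replicates)) {
    td <- run_single_trial(config, seed = rep_seeds[i])
    an <- analyze_trial(td, config, methods = methods)
    if (is.null(summary_acc)) {
      summary_acc <- an$summary
      summary_acc[sum_cols] <- lapply(summary_acc[sum_cols], as.numeric)
      risk_key <- an$risk[, c("method", "stratum")]
      risk_mat <- matrix(NA_real_, nrow = nrow(an$risk),
                         ncol = n_replicates)
    } else {
      summary_acc[sum_cols] <- summary_acc[sum_cols] + an$summary[sum_cols]
    }
    risk_mat[, i] <- an$risk$risk_difference
    events_total[i] <- sum(td$women$detected)
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("replicate %d/%d", i, n_replicates))
    }
  }

  summary_mean <- summary_acc
  summary_mean[sum_cols] <- lapply(summary_mean[sum_cols],
                                   function(x) x / n_replicates)
  summary_mean$degenerate <- summary_mean$exposure <= 0
  summary_mean$hazard <- ifelse(summary_mean$exposure > 0,
                                100 * summary_mean$events /
                                  summary_mean$exposure, 0)

  risk <- risk_key
  risk$mean_risk_difference <- rowMeans(risk_mat)
  qs <- t(apply(risk_mat, 1, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  risk$ci_low <- qs[, 1]
  risk$ci_high <- qs[, 2]
  risk$p_R_lt_0 <- rowMeans(risk_mat < 0)
  risk$p_R_eq_0 <- rowMeans(risk_mat == 0)

  structure(list(
    n_replicates = n_replicates,
    seed = seed,
    summary = summary_mean,
    risk = risk,
    replicate_events = events_total,
    replicate_risk = if (keep_replicates) risk_mat else NULL,
    config = config
  ), class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf("<aggregate_result> %d replicates (seed %s)\n",
              x$n_replicates, format(x$seed)))
  cat(sprintf("  mean detected cancers per trial: %.1f\n",
              mean(x$replicate_events)))
  ov <- x$risk[x$risk$stratum == "overall_pooled", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-28s overall R = %+.4f (%.3f to %.3f), P(R<0) = %.3f\n",
                ov$method[i], ov$mean_risk_difference[i], ov$ci_low[i],
                ov$ci_high[i], ov$p_R_lt_0[i]))
  }
  invisible(x)
}

# Fetch one aggregate risk row.
agg_risk_row <- function(agg, method, stratum) {
  r <- agg$risk[agg$risk$method == method & agg$risk$stratum == stratum, ]
  if (nrow(r) != 1) stop("no unique risk row for ", method, "/", stratum)
  r
}

# Fetch one aggregate summary cell.
agg_summary_row <- function(agg, method, stratum, arm) {
  r <- agg$summary[agg$summary$method == method &
                     agg$summary$stratum == stratum &
                     agg$summary$arm == arm, ]
  if (nrow(r) != 1) stop("no unique summary row")
  r
}
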