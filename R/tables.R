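screening_group_label <- function(interval_years) {
  ifelse(is.na(interval_years), "No screening at this time",
    ifelse(interval_years == 0.5, "Every 6 months",
      ifelse(interval_years == 1, "Annual",
        ifelse(interval_years == 2, "Biennial",
          paste0("Every ", format(interval_years), " y")))))
}

#' Cancers by mode of detection (report table)
#'
#' Mean numbers of detected stage IIB+ cancers per trial by risk group
#' (labelled by the personalized-arm screening recommendation), mode of
#' detection and arm, under total-trial-time counting. The prevalent column
#' counts prevalent cancers present at randomization (whether or not they
#' are detected in-trial, which is why it is symmetric between arms);
#' total = screen-detected + clinically detected.
#'
#' @param agg an `aggregate_result`.
#' @return a `data.frame`, one row per screening group plus `All risk
#'   groups`.
#' @export
make_table3 <- function(agg) {
  cfg <- agg$config
  sm <- agg$summary[agg$summary$method == "total_time", ]
  labels <- screening_group_label(cfg$strata$interval_years)
  order_idx <- order(ifelse(is.na(cfg$strata$interval_years), Inf,
                            cfg$strata$interval_years))
  rows <- lapply(c(cfg$strata$name[order_idx], "overall"), function(s) {
    p <- sm[sm$stratum == s & sm$arm == "personalized", ]
    a <- sm[sm$stratum == s & sm$arm == "annual", ]
    data.frame(
      risk_group = if (s == "overall") "All risk groups"
                   else labels[match(s, cfg$strata$name)],
      prevalent_personalized = p$n_prevalent,
      prevalent_annual = a$n_prevalent,
      screen_detected_personalized = p$events_screen,
      screen_detected_annual = a$events_screen,
      clinically_detected_personalized = p$events_clinical,
      clinically_detected_annual = a$events_clinical,
      total_personalized = p$events,
      total_annual = a$events,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Expected trial results (report table)
#'
#' Mean events, exposure, hazard rates (per 100 person-years), mean risk
#' difference with across-replicate 95% percentile interval, P(R < 0), and
#' mammogram counts, per analysis method and risk stratum. Overall rows are
#' given both pooled (summed events and exposure per arm) and with
#' inverse-total-exposure stratum weighting (risk-difference columns only).
#'
#' @param agg an `aggregate_result`.
#' @return a long `data.frame`, one row per method x stratum.
#' @export
make_table4 <- function(agg) {
  cfg <- agg$config
  order_idx <- order(ifelse(is.na(cfg$strata$interval_years), Inf,
                            cfg$strata$interval_years))
  strata_order <- c(cfg$strata$name[order_idx], "overall_pooled",
                    "overall_weighted")
  methods <- unique(agg$summary$method)
  rows <- list()
  for (m in methods) {
    for (s in strata_order) {
      rk <- agg_risk_row(agg, m, s)
      s_sum <- if (s %in% c("overall_pooled", "overall_weighted"))
        "overall" else s
      has_cells <- s != "overall_weighted"
      p <- if (has_cells) agg_summary_row(agg, m, s_sum, "personalized")
      a <- if (has_cells) agg_summary_row(agg, m, s_sum, "annual")
      rows[[length(rows) + 1L]] <- data.frame(
        method = m,
        stratum = s,
        events_personalized = if (has_cells) p$events else NA_real_,
        events_annual = if (has_cells) a$events else NA_real_,
        exposure_personalized = if (has_cells) p$exposure else NA_real_,
        exposure_annual = if (has_cells) a$exposure else NA_real_,
        hazard_personalized = if (has_cells) p$hazard else NA_real_,
        hazard_annual = if (has_cells) a$hazard else NA_real_,
        mean_risk_difference = rk$mean_risk_difference,
        ci_low = rk$ci_low,
        ci_high = rk$ci_high,
        p_R_lt_0 = rk$p_R_lt_0,
        mammograms_personalized = if (has_cells) p$n_mammograms else NA_real_,
        mammograms_annual = if (has_cells) a$n_mammograms else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_report_table <- function(tab, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
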