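#' Total-trial-time exposure
#'
#' Exposure runs from study entry to cancer detection or study exit (trial
#' end); every woman and every detected event is counted.
#'
#' @param women the `women` table of a `trial_data`.
#' @param trial_end trial end time.
#' @return numeric vector of person-years.
#' @export
exposure_total_time <- function(women, trial_end) {
  ifelse(women$detected, women$detection_time, trial_end) - women$entry_time
}

#' Complete-screening-cycles exposure and event counting
#'
#' For women on a screening schedule, follow-up is restricted to complete
#' screening cycles: an event (screen- or clinically detected) is counted
#' only if its detection time falls on or before the woman's last scheduled
#' screen; exposure runs from entry to detection when the event is counted,
#' otherwise to the last scheduled screen. Women with zero completed screens
#' contribute nothing. Unscreened personalized-arm women are included only
#' if they are due an exit mammogram (enrolled long enough); their cycle is
#' entry to the exit mammogram, so all their detected events are counted.
#'
#' @param women the `women` table of a `trial_data`.
#' @param trial_end trial end time.
#' @return data.frame with `included`, `exposure`, `event_counted`.
#' @export
exposure_complete_cycles <- function(women, trial_end) {
  screened <- !is.na(women$interval)
  has_cycle <- screened & women$n_screens_schedule > 0
  last <- women$last_screen_time

  counted <- rep(FALSE, nrow(women))
  exposure <- rep(0, nrow(women))
  included <- rep(FALSE, nrow(women))

  counted[has_cycle] <- women$detected[has_cycle] &
    women$detection_time[has_cycle] <= last[has_cycle]
  exposure[has_cycle] <- ifelse(
    counted[has_cycle],
    women$detection_time[has_cycle] - women$entry_time[has_cycle],
    last[has_cycle] - women$entry_time[has_cycle])
  included[has_cycle] <- TRUE

  exit_elig <- !screened & !is.na(women$exit_time)
  counted[exit_elig] <- women$detected[exit_elig]
  exposure[exit_elig] <- ifelse(
    women$detected[exit_elig],
    women$detection_time[exit_elig] - women$entry_time[exit_elig],
    trial_end - women$entry_time[exit_elig])
  included[exit_elig] <- TRUE

  data.frame(included = included, exposure = exposure,
             event_counted = counted)
}

#' Entry-mammogram analysis variant
#'
#' Marks prevalent-cancer events as excluded (analytically equivalent to
#' giving every woman a study entry mammogram) and adds one entry mammogram
#' to the mammogram count of every woman on a screening schedule. Excluded
#' women keep their exposure as non-cases; only their events are removed.
#'
#' @param trialdata a `trial_data`.
#' @return a `trial_data` with `event_excluded` set and mammogram counts
#'   incremented.
#' @export
apply_entry_mammogram_variant <- function(trialdata) {
  w <- trialdata$women
  w$event_excluded <- w$prevalent & w$detected
  w$n_mammograms <- w$n_mammograms + as.integer(!is.na(w$interval))
  trialdata$women <- w
  trialdata$entry_mammogram_variant <- TRUE
  trialdata
}

# Per-woman event/exposure table for one analysis method.
method_woman_table <- function(trialdata, method) {
  w <- trialdata$women
  tend <- trialdata$trial_end
  base <- data.frame(stratum = w$stratum, arm = w$arm,
                     mode = w$mode, prevalent = w$prevalent,
                     mammograms = w$n_mammograms)
  if (method == "total_time") {
    base$included <- rep(TRUE, nrow(w))
    base$event <- w$detected
    base$exposure <- exposure_total_time(w, tend)
  } else if (method == "complete_cycles") {
    cc <- exposure_complete_cycles(w, tend)
    base$included <- cc$included
    base$event <- cc$event_counted
    base$exposure <- cc$exposure
  } else if (method == "complete_cycles_entry_mammo") {
    variant <- if (isTRUE(trialdata$entry_mammogram_variant)) trialdata
               else apply_entry_mammogram_variant(trialdata)
    wv <- variant$women
    cc <- exposure_complete_cycles(wv, tend)
    base$included <- cc$included
    base$event <- cc$event_counted & !wv$event_excluded
    base$exposure <- cc$exposure
    base$mammograms <- wv$n_mammograms
  } else {
    stop("unknown analysis method: ", method, call. = FALSE)
  }
  base
}

# Sum per stratum x arm with all cells present even when empty.
summarize_cells <- function(tab, strata_names) {
  ns <- length(strata_names)
  cell <- (tab$stratum - 1L) * 2L +
    ifelse(tab$arm == "personalized", 1L, 2L)
  ncell <- 2L * ns
  sum_cell <- function(x) {
    out <- numeric(ncell)
    if (length(x) > 0) {
      t <- rowsum(as.numeric(x), cell)
      out[as.integer(rownames(t))] <- t[, 1]
    }
    out
  }
  ev <- tab$event
  data.frame(
    stratum = rep(strata_names, each = 2L),
    arm = rep(c("personalized", "annual"), ns),
    n_women = sum_cell(rep(1, nrow(tab))),
    n_included = sum_cell(tab$included),
    n_prevalent = sum_cell(tab$prevalent),
    events = sum_cell(ev),
    events_screen = sum_cell(ev & tab$mode == "screen"),
    events_clinical = sum_cell(ev & tab$mode == "clinical"),
    events_prevalent = sum_cell(ev & tab$prevalent),
    exposure = sum_cell(tab$exposure),
    n_mammograms = sum_cell(tab$mammograms),
    stringsAsFactors = FALSE
  )
}

add_overall_and_hazard <- function(sm) {
  agg_cols <- c("n_women", "n_included", "n_prevalent", "events",
                "events_screen", "events_clinical", "events_prevalent",
                "exposure", "n_mammograms")
  overall <- do.call(rbind, lapply(c("personalized", "annual"), function(a) {
    rows <- sm[sm$arm == a, ]
    out <- rows[1, , drop = FALSE]
    out$stratum <- "overall"
    out[agg_cols] <- lapply(rows[agg_cols], sum)
    out
  }))
  sm <- rbind(sm, overall)
  sm$degenerate <- sm$exposure <= 0
  sm$hazard <- ifelse(sm$exposure > 0, 100 * sm$events / sm$exposure, 0)
  rownames(sm) <- NULL
  sm
}

# Risk differences (annual minus personalized, per 100 person-years) per
# stratum plus the two overall combinations.
risk_table <- function(sm, strata_names) {
  h <- function(stratum, arm) {
    sm$hazard[sm$stratum == stratum & sm$arm == arm]
  }
  e <- function(stratum, arm) {
    sm$exposure[sm$stratum == stratum & sm$arm == arm]
  }
  haz_a <- vapply(strata_names, h, numeric(1), arm = "annual")
  haz_p <- vapply(strata_names, h, numeric(1), arm = "personalized")
  r_s <- haz_a - haz_p

  pooled_a <- h("overall", "annual")
  pooled_p <- h("overall", "personalized")

  w_s <- vapply(strata_names, function(s) {
    tot <- e(s, "annual") + e(s, "personalized")
    if (tot > 0) 1 / tot else 0
  }, numeric(1))
  r_weighted <- if (sum(w_s) > 0) sum(w_s * r_s) / sum(w_s) else 0

  data.frame(
    stratum = c(strata_names, "overall_pooled", "overall_weighted"),
    hazard_annual = c(haz_a, pooled_a, NA_real_),
    hazard_personalized = c(haz_p, pooled_p, NA_real_),
    risk_difference = c(r_s, pooled_a - pooled_p, r_weighted),
    stringsAsFactors = FALSE
  )
}

#' Analyze one virtual trial with all candidate estimators
#'
#' Applies the four candidate primary-analysis methods — `total_time`,
#' `complete_cycles`, `complete_cycles_entry_mammo`, and `hybrid` (complete
#' cycles for strata screened in the personalized arm, total trial time for
#' the unscreened stratum) — and computes per-stratum-by-arm event counts,
#' person-year exposures, hazards per 100 person-years, and risk
#' differences R = hazard(annual) - hazard(personalized). Overall risk
#' differences are combined both by pooling events and exposure across
#' strata and by inverse-total-exposure stratum weighting.
#'
#' @param trialdata a `trial_data`.
#' @param config the `trial_config` used to simulate it.
#' @param methods subset of methods to compute (hybrid requires both of its
#'   ingredients; default all four).
#' @return an object of class `trial_analysis`: list with `summary` (one
#'   row per method x stratum x arm, including `"overall"` rows) and `risk`
#'   (one row per method x stratum plus pooled and weighted overall rows).
#' @export
analyze_trial <- function(trialdata, config,
                          methods = c("total_time", "complete_cycles",
                                      "complete_cycles_entry_mammo",
                                      "hybrid")) {
  strata_names <- config$strata$name
  base_methods <- setdiff(methods, "hybrid")
  if ("hybrid" %in% methods) {
    base_methods <- union(base_methods, c("total_time", "complete_cycles"))
  }
  sums <- lapply(base_methods, function(m) {
    sm <- summarize_cells(method_woman_table(trialdata, m), strata_names)
    add_overall_and_hazard(sm)
  })
  names(sums) <- base_methods

  if ("hybrid" %in% methods) {
    unscreened <- strata_names[is.na(config$strata$interval_years)]
    cc <- sums[["complete_cycles"]]
    tt <- sums[["total_time"]]
    take_tt <- tt$stratum %in% unscreened
    take_cc <- !(cc$stratum %in% c(unscreened, "overall"))
    hy <- rbind(cc[take_cc, ], tt[take_tt, ])
    hy <- hy[order(match(hy$stratum, strata_names),
                   match(hy$arm, c("personalized", "annual"))), ]
    hy$hazard <- NULL
    hy$degenerate <- NULL
    sums[["hybrid"]] <- add_overall_and_hazard(hy)
  }

  sums <- sums[intersect(c("total_time", "complete_cycles",
                           "complete_cycles_entry_mammo", "hybrid"),
                         names(sums))]
  summary <- do.call(rbind, lapply(names(sums), function(m) {
    cbind(method = m, sums[[m]], stringsAsFactors = FALSE)
  }))
  risk <- do.call(rbind, lapply(names(sums), function(m) {
    cbind(method = m, risk_table(sums[[m]], strata_names),
          stringsAsFactors = FALSE)
  }))
  rownames(summary) <- rownames(risk) <- NULL
  structure(list(summary = summary, risk = risk,
                 strata = strata_names),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("<trial_analysis> methods:",
      paste(unique(x$summary$method), collapse = ", "), "\n")
  ov <- x$risk[x$risk$stratum == "overall_pooled", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-28s overall R = %+.4f per 100 py\n",
                ov$method[i], ov$risk_difference[i]))
  }
  invisible(x)
}

#' Write an analysis as a tidy CSV
#'
#' @param analysis a `trial_analysis`.
#' @param path file path.
#' @export
write_analysis <- function(analysis, path) {
  rd <- analysis$risk[, c("method", "stratum", "risk_difference")]
  sm <- merge(analysis$summary, rd,
              by = c("method", "stratum"), all.x = TRUE, sort = FALSE)
  utils::write.csv(sm, path, row.names = FALSE)
  invisible(path)
}
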