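#' Screening interval assigned to a woman
#'
#' Annual-arm women are screened at `annual_arm_interval_years` regardless of
#' stratum; personalized-arm women follow their stratum's recommended
#' interval (`NA` = no screening).
#'
#' @param arm character vector, `"annual"` or `"personalized"`.
#' @param stratum integer stratum indices.
#' @param config a `trial_config`.
#' @return numeric vector of intervals in years (`NA` for no screening).
#' @export
assigned_interval <- function(arm, stratum, config) {
  ifelse(arm == "annual",
         config$annual_arm_interval_years,
         config$strata$interval_years[stratum])
}

#' First planned screen (deterministic form)
#'
#' The first on-study screen is planned `max(0, interval - t_last)` years
#' after entry, where `t_last` is the time since the woman's last pre-entry
#' mammogram. With `t_last = 0` (the default configuration draws no credit)
#' the first screen is planned one full interval after entry.
#'
#' @param entry absolute entry times.
#' @param interval screening interval in years.
#' @param t_last time since last pre-entry mammogram, in years.
#' @return absolute planned times.
#' @export
first_planned_screen <- function(entry, interval, t_last = 0) {
  entry + pmax(0, interval - t_last)
}

#' First planned screen (stochastic form)
#'
#' Draws `t_last ~ Uniform(0, last_premammogram_max_years)` and applies
#' [first_planned_screen()]. With the default configuration the upper bound
#' is 0, so the draw degenerates to `entry + interval`.
#'
#' @inheritParams first_planned_screen
#' @param config a `trial_config`.
#' @return absolute planned times.
#' @export
simulate_first_planned_screen <- function(entry, interval, config) {
  m <- config$last_premammogram_max_years
  t_last <- if (m > 0) stats::runif(length(entry), 0, m) else
    rep(0, length(entry))
  first_planned_screen(entry, interval, t_last)
}

#' Half-normal noncompliance delays
#'
#' Screening delays are `|Normal(0, sigma)|` (a normal truncated to the
#' nonnegative half-line): delays only ever push a screen later. With
#' sigma = 4 months, 55% of delays fall within 3 months and 87% within
#' 6 months.
#'
#' @param n number of draws.
#' @param sd_months sigma in months.
#' @return delays in years.
#' @export
simulate_noncompliance_delay <- function(n, sd_months) {
  if (sd_months <= 0) stop("sd_months must be positive", call. = FALSE)
  abs(stats::rnorm(n, mean = 0, sd = sd_months / 12))
}

#' Realized screen times for one woman (deterministic core)
#'
#' Iterates the schedule: actual_k = planned_k + delay_k; the next screen is
#' planned one interval after the *actual* time; a screen whose actual time
#' exceeds `trial_end` does not occur and ends the schedule.
#'
#' @param first_planned absolute time of the first planned screen.
#' @param interval screening interval in years.
#' @param trial_end trial end time.
#' @param delays vector of per-screen delays (years); its length bounds the
#'   number of screens considered.
#' @return numeric vector of actual screen times (possibly empty).
#' @export
screen_times_from_delays <- function(first_planned, interval, trial_end,
                                     delays) {
  times <- numeric(0)
  planned <- first_planned
  for (d in delays) {
    actual <- planned + d
    if (is.na(actual) || actual > trial_end) break
    times <- c(times, actual)
    planned <- actual + interval
  }
  times
}

#' Realized screen times for one woman (stochastic form)
#'
#' Draws the first planned screen and per-screen half-normal delays from the
#' configuration, then applies [screen_times_from_delays()].
#'
#' @param entry absolute entry time (scalar).
#' @param interval screening interval in years (scalar, not `NA`).
#' @param trial_end trial end time.
#' @param config a `trial_config`.
#' @return numeric vector of actual screen times.
#' @export
simulate_screen_times <- function(entry, interval, trial_end, config) {
  stopifnot(length(entry) == 1, !is.na(interval))
  fp <- simulate_first_planned_screen(entry, interval, config)
  kmax <- max_screen_count(config)
  delays <- simulate_noncompliance_delay(kmax, config$noncompliance_sd_months)
  screen_times_from_delays(fp, interval, trial_end, delays)
}

# Upper bound on the number of scheduled screens any woman can attend:
# screens are nonnegative, spaced at least one (minimum) interval apart and
# capped at trial_end.
max_screen_count <- function(config) {
  ints <- c(config$annual_arm_interval_years,
            config$strata$interval_years)
  ints <- ints[!is.na(ints)]
  max(1L, as.integer(floor(config$trial_end_years / min(ints))) + 1L)
}

#' Exit-mammogram times
#'
#' Only personalized-arm women in the unscreened stratum receive an exit
#' mammogram, at trial end, and only if they have been enrolled for at least
#' `exit_mammogram_min_enrollment_years`. Everyone else gets `NA`.
#'
#' @param cohort a cohort `data.frame`.
#' @param config a `trial_config`.
#' @return numeric vector (absolute times or `NA`).
#' @export
exit_mammogram_times <- function(cohort, config) {
  unscreened <- is.na(config$strata$interval_years[cohort$stratum])
  eligible <- cohort$arm == "personalized" & unscreened &
    (config$trial_end_years - cohort$entry_time >=
       config$exit_mammogram_min_enrollment_years)
  ifelse(eligible, config$trial_end_years, NA_real_)
}

#' Detection outcome for one woman
#'
#' Scalar form of the detection rule applied by [realize_trial()]: scan the
#' mammogram times in order; a mammogram at time s with
#' `t_detectable <= s < t_clinical` detects with probability `sensitivity`;
#' with no successful mammogram, a cancer clinically detectable before
#' trial end is clinically detected at that time.
#'
#' @param mammogram_times increasing mammogram times (screens and, last,
#'   any exit mammogram); may be empty.
#' @param t_detectable,t_clinical the woman's natural-history clocks.
#' @param trial_end trial end time.
#' @param sensitivity per-screen detection probability.
#' @param detect_u optional uniforms (one per mammogram) deciding each
#'   screen's Bernoulli trial; omitted means certain detection in-window.
#' @return list with `detected`, `mode` (screen/clinical/none) and
#'   `detection_time` (`NA` if none).
#' @export
detect_cancer <- function(mammogram_times, t_detectable, t_clinical,
                          trial_end, sensitivity = 1, detect_u = NULL) {
  for (j in seq_along(mammogram_times)) {
    s <- mammogram_times[j]
    if (s >= t_detectable && s < t_clinical) {
      hit <- if (is.null(detect_u)) sensitivity >= 1 ||
        stats::runif(1) < sensitivity else detect_u[j] < sensitivity
      if (hit) {
        return(list(detected = TRUE, mode = "screen", detection_time = s))
      }
    }
  }
  if (t_clinical <= trial_end) {
    return(list(detected = TRUE, mode = "clinical",
                detection_time = t_clinical))
  }
  list(detected = FALSE, mode = "none", detection_time = NA_real_)
}

#' Draw the screening-stage randomness for a whole cohort
#'
#' Pre-draws, in a fixed documented order, every random quantity the
#' screening stage needs: the time-since-last-mammogram credit (`t_last`),
#' an n-by-K matrix of half-normal delays (column k = a woman's k-th
#' scheduled screen), and — only when some stratum has sensitivity below 1 —
#' an n-by-(K+1) matrix of detection uniforms (last column = the exit
#' mammogram). Pre-drawing makes the downstream realization deterministic,
#' which is what the event-loop/vectorized equivalence tests exploit.
#'
#' @param n cohort size.
#' @param config a `trial_config`.
#' @return list with `t_last`, `delays`, `detect_u` (or `NULL`).
#' @export
draw_screening_randomness <- function(n, config) {
  k <- max_screen_count(config)
  m <- config$last_premammogram_max_years
  t_last <- if (m > 0) stats::runif(n, 0, m) else rep(0, n)
  delays <- matrix(simulate_noncompliance_delay(
    n * k, config$noncompliance_sd_months), nrow = n, ncol = k)
  detect_u <- NULL
  if (any(config$strata$sensitivity < 1)) {
    detect_u <- matrix(stats::runif(n * (k + 1L)), nrow = n, ncol = k + 1L)
  }
  list(t_last = t_last, delays = delays, detect_u = detect_u)
}

#' Realize screening and detection for a cohort (deterministic)
#'
#' Given a cohort and pre-drawn randomness, builds the full screening
#' schedule, applies the detection rules, and returns the complete trial
#' data. Detection scans a woman's mammograms (scheduled screens, then the
#' exit mammogram) in time order; a mammogram at time s with
#' `t_detectable <= s < t_clinical` detects with probability equal to the
#' stratum sensitivity (independent Bernoulli per screen). If no mammogram
#' succeeds and the cancer becomes clinically detectable before trial end,
#' it is clinically detected at that time. A woman attends no further
#' mammograms after her detection; women never detected attend their full
#' schedule. The full schedule (including screens after a detection) is
#' retained as the cycle structure used by the complete-screening-cycles
#' estimator.
#'
#' @param cohort a cohort `data.frame`.
#' @param draws output of [draw_screening_randomness()].
#' @param config a `trial_config`.
#' @return an object of class `trial_data`: list with `women` (one row per
#'   woman), `screens` (n-by-K matrix of scheduled screen times, `NA`
#'   beyond the schedule) and `trial_end`.
#' @export
realize_trial <- function(cohort, draws, config) {
  n <- nrow(cohort)
  tend <- config$trial_end_years
  k_max <- ncol(draws$delays)

  interval <- assigned_interval(cohort$arm, cohort$stratum, config)
  first_planned <- ifelse(
    is.na(interval), NA_real_,
    first_planned_screen(cohort$entry_time, interval, draws$t_last))

  screens <- matrix(NA_real_, nrow = n, ncol = k_max)
  planned <- first_planned
  for (k in seq_len(k_max)) {
    actual <- planned + draws$delays[, k]
    ok <- which(!is.na(actual) & actual <= tend)
    screens[ok, k] <- actual[ok]
    planned <- rep(NA_real_, n)
    planned[ok] <- actual[ok] + interval[ok]
  }

  exit_time <- exit_mammogram_times(cohort, config)
  sens <- config$strata$sensitivity[cohort$stratum]
  t_det <- cohort$t_detectable
  t_clin <- cohort$t_clinical

  candidates <- cbind(screens, exit_time)
  det_time <- rep(NA_real_, n)
  det_col <- rep(NA_integer_, n)
  undetected <- rep(TRUE, n)
  for (k in seq_len(k_max + 1L)) {
    cand <- candidates[, k]
    hit <- undetected & !is.na(cand) & cand >= t_det & cand < t_clin
    if (!is.null(draws$detect_u)) {
      hit <- hit & draws$detect_u[, k] < sens
    }
    det_time[hit] <- cand[hit]
    det_col[hit] <- k
    undetected[hit] <- FALSE
  }
  mode <- rep("none", n)
  mode[!undetected] <- "screen"
  clinical <- undetected & t_clin <= tend
  mode[clinical] <- "clinical"
  det_time[clinical] <- t_clin[clinical]
  detected <- mode != "none"

  n_sched <- rowSums(!is.na(screens))
  last_sched <- if (n > 0) {
    do.call(pmax, c(lapply(seq_len(k_max), function(k) screens[, k]),
                    list(na.rm = TRUE)))
  } else numeric(0)

  cap <- ifelse(detected, det_time, Inf)
  attended <- rowSums(sweep(screens, 1, cap, "<=") & !is.na(screens),
                      na.rm = TRUE)
  exit_attended <- !is.na(exit_time) &
    (!detected | (!is.na(det_col) & det_col == k_max + 1L))
  n_mammograms <- as.integer(attended) + as.integer(exit_attended)

  first_screen_time <- ifelse(n_sched > 0, screens[, 1], exit_time)
  detected_at_first <- detected & mode == "screen" &
    !is.na(first_screen_time) & det_time == first_screen_time

  women <- cohort
  women$interval <- interval
  women$first_planned <- first_planned
  women$n_screens_schedule <- as.integer(n_sched)
  women$last_screen_time <- last_sched
  women$exit_time <- exit_time
  women$exit_attended <- exit_attended
  women$n_mammograms <- n_mammograms
  women$detected <- detected
  women$mode <- mode
  women$detection_time <- det_time
  women$detected_at_first_screen <- detected_at_first
  women$prevalent_at_detection <- cohort$prevalent & detected

  structure(list(women = women, screens = screens, trial_end = tend),
            class = "trial_data")
}

#' Run one virtual trial
#'
#' Simulates the cohort (entry, arm, stratum, prevalence, natural history),
#' draws the screening randomness and realizes screening and detection.
#' Deterministic under a fixed `seed`.
#'
#' @param config a `trial_config`.
#' @param seed optional integer seed (falls back to `config$seed`).
#' @return a `trial_data` object.
#' @export
run_single_trial <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  cohort <- simulate_cohort(config)
  draws <- draw_screening_randomness(nrow(cohort), config)
  realize_trial(cohort, draws, config)
}

#' @export
print.trial_data <- function(x, ...) {
  w <- x$women
  cat(sprintf("<trial_data> %d women, trial end %.2f y\n", nrow(w),
              x$trial_end))
  cat(sprintf("  detected: %d (screen %d, clinical %d; prevalent %d)\n",
              sum(w$detected), sum(w$mode == "screen"),
              sum(w$mode == "clinical"), sum(w$prevalent_at_detection)))
  cat(sprintf("  mammograms: %d (annual arm %d, personalized arm %d)\n",
              sum(w$n_mammograms), sum(w$n_mammograms[w$arm == "annual"]),
              sum(w$n_mammograms[w$arm == "personalized"])))
  invisible(x)
}

#' Serialize trial data to CSV
#'
#' One row per woman; scheduled screen times are collapsed into a single
#' `;`-separated column. [read_trial_data()] restores the object.
#'
#' @param trialdata a `trial_data`.
#' @param path file path.
#' @export
write_trial_data <- function(trialdata, path) {
  w <- trialdata$women
  w$screen_times <- apply(trialdata$screens, 1, function(r) {
    paste(format(r[!is.na(r)], digits = 17, trim = TRUE), collapse = ";")
  })
  w$trial_end <- trialdata$trial_end
  utils::write.csv(w, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- c("entry_time", "t_detectable", "t_clinical", "interval",
                "first_planned", "last_screen_time", "exit_time",
                "detection_time")
  for (col in intersect(num_cols, names(w))) w[[col]] <- as.numeric(w[[col]])
  int_cols <- c("id", "stratum", "n_screens_schedule", "n_mammograms")
  for (col in intersect(int_cols, names(w))) w[[col]] <- as.integer(w[[col]])
  lgl_cols <- c("prevalent", "exit_attended", "detected",
                "detected_at_first_screen", "prevalent_at_detection")
  for (col in intersect(lgl_cols, names(w))) w[[col]] <- as.logical(w[[col]])
  w$screen_times <- as.character(w$screen_times)
  parts <- strsplit(ifelse(is.na(w$screen_times), "", w$screen_times), ";",
                    fixed = TRUE)
  k <- max(1L, max(lengths(parts)))
  screens <- matrix(NA_real_, nrow = nrow(w), ncol = k)
  for (i in seq_along(parts)) {
    v <- as.numeric(parts[[i]])
    if (length(v) > 0) screens[i, seq_along(v)] <- v
  }
  tend <- if (nrow(w) > 0) w$trial_end[1] else NA_real_
  w$screen_times <- NULL
  w$trial_end <- NULL
  structure(list(women = w, screens = screens, trial_end = tend),
            class = "trial_data")
}
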