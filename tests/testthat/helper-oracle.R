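# Straightforward per-woman event-loop reference implementation of the
# screening/detection stage. Independent of the vectorized production code:
# it consumes the same pre-drawn randomness (delays matrix, detection
# uniforms) but re-derives schedules and detections one woman at a time.

oracle_realize <- function(cohort, draws, config) {
  tend <- config$trial_end_years
  n <- nrow(cohort)
  k_max <- ncol(draws$delays)
  out <- data.frame(
    n_screens_schedule = integer(n), last_screen_time = rep(NA_real_, n),
    exit_time = rep(NA_real_, n), exit_attended = logical(n),
    n_mammograms = integer(n), detected = logical(n),
    mode = character(n), detection_time = rep(NA_real_, n),
    detected_at_first_screen = logical(n)
  )
  for (i in seq_len(n)) {
    w <- cohort[i, ]
    interval <- if (w$arm == "annual") {
      config$annual_arm_interval_years
    } else {
      config$strata$interval_years[w$stratum]
    }
    screens <- numeric(0)
    if (!is.na(interval)) {
      planned <- w$entry_time + max(0, interval - draws$t_last[i])
      for (k in seq_len(k_max)) {
        actual <- planned + draws$delays[i, k]
        if (actual > tend) break
        screens <- c(screens, actual)
        planned <- actual + interval
      }
    }
    exit_t <- NA_real_
    if (w$arm == "personalized" && is.na(interval) &&
        tend - w$entry_time >= config$exit_mammogram_min_enrollment_years) {
      exit_t <- tend
    }
    sens <- config$strata$sensitivity[w$stratum]
    mams <- c(screens, exit_t)
    ucols <- c(seq_along(screens), k_max + 1L)
    keep <- !is.na(mams)
    mams <- mams[keep]
    ucols <- ucols[keep]

    det_time <- NA_real_
    det_at_exit <- FALSE
    det_j <- NA_integer_
    for (j in seq_along(mams)) {
      if (mams[j] >= w$t_detectable && mams[j] < w$t_clinical) {
        u_ok <- if (is.null(draws$detect_u)) TRUE
                else draws$detect_u[i, ucols[j]] < sens
        if (u_ok) {
          det_time <- mams[j]
          det_at_exit <- ucols[j] == k_max + 1L
          det_j <- j
          break
        }
      }
    }
    mode <- "none"
    if (!is.na(det_time)) {
      mode <- "screen"
    } else if (w$t_clinical <= tend) {
      mode <- "clinical"
      det_time <- w$t_clinical
    }
    detected <- mode != "none"

    attended <- if (detected) sum(screens <= det_time) else length(screens)
    exit_attended <- !is.na(exit_t) && (!detected || det_at_exit)

    out$n_screens_schedule[i] <- length(screens)
    out$last_screen_time[i] <- if (length(screens) > 0) max(screens)
                               else NA_real_
    out$exit_time[i] <- exit_t
    out$exit_attended[i] <- exit_attended
    out$n_mammograms[i] <- attended + as.integer(exit_attended)
    out$detected[i] <- detected
    out$mode[i] <- mode
    out$detection_time[i] <- det_time
    out$detected_at_first_screen[i] <- detected && mode == "screen" &&
      !is.na(det_j) && det_j == 1L
  }
  out
}
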