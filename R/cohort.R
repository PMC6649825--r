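#' Simulate staggered entry times
#'
#' Draws exactly `accrual_counts[j]` entry times uniformly within the j-th
#' accrual period. Times are absolute (years from trial start).
#'
#' @param config a `trial_config`.
#' @return numeric vector of length `n_total`.
#' @export
simulate_entry_times <- function(config) {
  b <- config$accrual_period_bounds
  counts <- config$accrual_counts
  unlist(lapply(seq_along(counts), function(j) {
    stats::runif(counts[j], min = b[j], max = b[j + 1])
  }), use.names = FALSE)
}

#' Randomize arms
#'
#' Simple (coin-flip) randomization: each woman is assigned to the
#' personalized arm independently with probability `ratio`. Per-arm counts
#' therefore vary binomially between replicates.
#'
#' @param n number of women.
#' @param ratio probability of the personalized arm, in (0,1).
#' @return character vector, `"annual"` or `"personalized"`.
#' @export
assign_arms <- function(n, ratio = 0.5) {
  if (ratio <= 0 || ratio >= 1)
    stop("randomization ratio must lie strictly in (0,1)", call. = FALSE)
  if (n == 0) return(character(0))
  ifelse(stats::runif(n) < ratio, "personalized", "annual")
}

#' Assign risk strata
#'
#' Independent multinomial draws over the stratum probabilities, independent
#' of arm.
#'
#' @param n number of women.
#' @param probabilities stratum probabilities (sum to 1).
#' @return integer vector of stratum indices.
#' @export
assign_strata <- function(n, probabilities) {
  if (n == 0) return(integer(0))
  sample.int(length(probabilities), n, replace = TRUE, prob = probabilities)
}

#' Per-woman prevalence probabilities
#'
#' Under the default `"hazard"` mode a woman is prevalent with probability
#' `1 - exp(-annual_hazard_s * prevalence_window_years)` — her cancer arose
#' during the window before entry and is still in its sojourn at entry —
#' so prevalence tracks stratum risk and averages about 0.05% over the
#' default cohort. The `"uniform"` mode applies `prevalence_prob` to every
#' woman regardless of stratum.
#'
#' @param strata stratum indices.
#' @param config a `trial_config`.
#' @return numeric vector of probabilities.
#' @export
prevalence_probability <- function(strata, config) {
  if (config$prevalence_mode == "hazard") {
    1 - exp(-config$strata$annual_hazard[strata] *
              config$prevalence_window_years)
  } else {
    rep(config$prevalence_prob, length(strata))
  }
}

#' Simulate natural history
#'
#' Seeds prevalent stage IIB+ cancers as per-woman Bernoulli trials with
#' [prevalence_probability()] at
#' randomization; non-prevalent women get an exponential time from entry to
#' mammogram-detectable cancer with the stratum's annual hazard as rate.
#' Every woman gets an exponential sojourn (rate log(2)/median), and the
#' clinical-detectability time is detectable time + sojourn. Prevalent women
#' have detectable time equal to entry; by memorylessness their sojourn draw
#' from entry is the residual sojourn. Onset times are drawn unconditionally
#' (most exceed the trial horizon); observability is decided later by the
#' screening process.
#'
#' @param entry_times absolute entry times.
#' @param arms arm labels from [assign_arms()].
#' @param strata stratum indices from [assign_strata()].
#' @param config a `trial_config`.
#' @return a `data.frame` (the cohort): id, entry_time, arm, stratum,
#'   prevalent, t_detectable, t_clinical.
#' @export
simulate_natural_history <- function(entry_times, arms, strata, config) {
  n <- length(entry_times)
  stopifnot(length(arms) == n, length(strata) == n)
  if (n == 0) {
    return(data.frame(id = integer(0), entry_time = numeric(0),
                      arm = character(0), stratum = integer(0),
                      prevalent = logical(0), t_detectable = numeric(0),
                      t_clinical = numeric(0)))
  }
  prevalent <- stats::runif(n) < prevalence_probability(strata, config)
  rate <- config$strata$annual_hazard[strata]
  onset_gap <- stats::rexp(n, rate = rate)
  sojourn <- stats::rexp(n, rate = log(2) / config$sojourn_median_years)
  t_detectable <- ifelse(prevalent, entry_times, entry_times + onset_gap)
  data.frame(
    id = seq_len(n),
    entry_time = entry_times,
    arm = arms,
    stratum = strata,
    prevalent = prevalent,
    t_detectable = t_detectable,
    t_clinical = t_detectable + sojourn
  )
}

#' Simulate a full cohort
#'
#' Composes [simulate_entry_times()], [assign_arms()], [assign_strata()] and
#' [simulate_natural_history()] under the current RNG state.
#'
#' @param config a `trial_config`.
#' @return a cohort `data.frame`.
#' @export
simulate_cohort <- function(config) {
  entry <- simulate_entry_times(config)
  arms <- assign_arms(length(entry), config$randomization_ratio)
  strata <- assign_strata(length(entry), config$strata$probability)
  simulate_natural_history(entry, arms, strata, config)
}

#' Write / read a cohort or trial table
#'
#' Plain-CSV round trip for fixture capture and debugging; one row per
#' woman.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `read_woman_table` returns the data.frame.
#' @export
write_woman_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_woman_table
#' @export
read_woman_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
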