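#' Risk-stratum specifications
#'
#' Builds the stratum table used by [trial_config()]. Each row describes one
#' risk stratum: its share of the cohort, its annual hazard of developing a
#' mammogram-detectable stage IIB+ cancer (probability scale per year,
#' interpreted as an exponential rate), the screening interval recommended in
#' the personalized arm (`NA` = no screening), and the per-screen mammographic
#' sensitivity.
#'
#' @param name character vector of stratum labels.
#' @param probability fractions of the cohort, must sum to 1.
#' @param annual_hazard per-year hazard of mammogram-detectable cancer.
#' @param interval_years personalized-arm screening interval in years
#'   (`NA` for no screening). At most one stratum may be unscreened.
#' @param sensitivity per-screen detection probability in (0, 1].
#' @return a `data.frame` with one row per stratum.
#' @export
stratum_spec <- function(name, probability, annual_hazard, interval_years,
                         sensitivity = 1) {
  data.frame(
    name = as.character(name),
    probability = as.numeric(probability),
    annual_hazard = as.numeric(annual_hazard),
    interval_years = as.numeric(interval_years),
    sensitivity = rep_len(as.numeric(sensitivity), length(name)),
    stringsAsFactors = FALSE
  )
}

#' Construct and validate a trial configuration
#'
#' All parameters of one virtual trial. Times are in years measured from
#' trial start (t = 0); entry times and all per-woman event times are
#' absolute. Defaults are the base-case parameter set of the WISDOM-style
#' design (see [default_wisdom_config()]).
#'
#' @param n_total number of randomized women.
#' @param accrual_counts women entering in each accrual period.
#' @param accrual_period_bounds period boundaries (years from trial start);
#'   length `length(accrual_counts) + 1`, strictly increasing, starting at 0.
#' @param randomization_ratio probability of assignment to the personalized
#'   arm (simple randomization).
#' @param trial_end_years total trial time.
#' @param prevalence_mode how prevalent stage IIB+ cancers are seeded at
#'   randomization. `"hazard"` (default): a woman in stratum s is prevalent
#'   with probability `1 - exp(-annual_hazard_s * prevalence_window_years)`,
#'   i.e. her cancer arose in the window before entry — prevalence tracks
#'   risk, with a cohort-average of about 0.05% under the default strata.
#'   `"uniform"`: the same Bernoulli probability `prevalence_prob` for
#'   every woman.
#' @param prevalence_prob prevalence probability used by the `"uniform"`
#'   mode (and the cohort-average prevalence it mirrors).
#' @param prevalence_window_years onset window used by the `"hazard"` mode.
#' @param sojourn_median_years median sojourn time (mammogram-detectable to
#'   clinically detectable).
#' @param noncompliance_sd_months sigma of the half-normal screening delay,
#'   in months.
#' @param annual_arm_interval_years screening interval in the annual arm.
#' @param exit_mammogram_min_enrollment_years minimum enrollment for the
#'   exit mammogram given to unscreened personalized-arm women.
#' @param last_premammogram_max_years upper bound of the uniform
#'   time-since-last-mammogram draw used to schedule the first on-study
#'   screen. With the default 0 the first screen is planned one full
#'   interval after entry.
#' @param strata stratum table from [stratum_spec()].
#' @param noninferiority_margin absolute risk margin (held as a constant,
#'   no testing machinery attached).
#' @param seed optional integer seed stored with the configuration.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(n_total = 65000L,
                         accrual_counts = c(5000L, 25000L, 20000L, 15000L),
                         accrual_period_bounds = c(0, 1, 2, 3, 4),
                         randomization_ratio = 0.5,
                         trial_end_years = 4.5,
                         prevalence_mode = c("hazard", "uniform"),
                         prevalence_prob = 0.0005,
                         prevalence_window_years = 1,
                         sojourn_median_years = 1.5,
                         noncompliance_sd_months = 4,
                         annual_arm_interval_years = 1,
                         exit_mammogram_min_enrollment_years = 2,
                         last_premammogram_max_years = 0,
                         strata = default_strata(),
                         noninferiority_margin = 0.0005,
                         seed = NULL) {
  cfg <- structure(
    list(
      n_total = as.integer(n_total),
      accrual_counts = as.integer(accrual_counts),
      accrual_period_bounds = as.numeric(accrual_period_bounds),
      randomization_ratio = as.numeric(randomization_ratio),
      trial_end_years = as.numeric(trial_end_years),
      prevalence_mode = match.arg(prevalence_mode),
      prevalence_prob = as.numeric(prevalence_prob),
      prevalence_window_years = as.numeric(prevalence_window_years),
      sojourn_median_years = as.numeric(sojourn_median_years),
      noncompliance_sd_months = as.numeric(noncompliance_sd_months),
      annual_arm_interval_years = as.numeric(annual_arm_interval_years),
      exit_mammogram_min_enrollment_years =
        as.numeric(exit_mammogram_min_enrollment_years),
      last_premammogram_max_years = as.numeric(last_premammogram_max_years),
      strata = strata,
      noninferiority_margin = as.numeric(noninferiority_margin),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "trial_config"
  )
  validate_config(cfg)
  cfg
}

#' Default stratum table
#'
#' Four risk strata (lowest, average, elevated, highest) with cohort shares
#' 28.9/40.4/28.2/2.5%, annual hazards 0.0198/0.0414/0.0774/0.2808%,
#' personalized-arm intervals none/2y/1y/6mo, and sensitivity 1 everywhere.
#'
#' @return a stratum `data.frame`.
#' @export
default_strata <- function() {
  stratum_spec(
    name = c("lowest", "average", "elevated", "highest"),
    probability = c(0.289, 0.404, 0.282, 0.025),
    annual_hazard = c(0.000198, 0.000414, 0.000774, 0.002808),
    interval_years = c(NA, 2, 1, 0.5),
    sensitivity = 1
  )
}

#' Default trial configuration
#'
#' The base-case parameter set: 65 000 women accrued 5000/25 000/20 000/
#' 15 000 over four one-year periods, 1:1 randomization, 4.5-year trial,
#' 0.05% prevalence, 18-month median sojourn, half-normal noncompliance
#' delays with sigma 4 months, and the four default risk strata.
#'
#' @return a `trial_config`.
#' @export
default_wisdom_config <- function() trial_config()

validate_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  s <- cfg$strata
  required <- c("name", "probability", "annual_hazard", "interval_years",
                "sensitivity")
  if (!is.data.frame(s) || !all(required %in% names(s)) || nrow(s) < 1)
    stop_field("strata", "must be a data.frame from stratum_spec()")
  if (any(s$probability <= 0) || any(s$probability >= 1))
    stop_field("strata$probability", "must lie in (0,1)")
  if (abs(sum(s$probability) - 1) > 1e-12)
    stop_field("strata$probability", "must sum to 1 (within 1e-12)")
  if (any(s$annual_hazard <= 0))
    stop_field("strata$annual_hazard", "must be positive")
  if (any(s$sensitivity <= 0 | s$sensitivity > 1))
    stop_field("strata$sensitivity", "must lie in (0,1]")
  if (sum(is.na(s$interval_years)) > 1)
    stop_field("strata$interval_years", "at most one stratum may be unscreened")
  if (any(s$interval_years[!is.na(s$interval_years)] <= 0))
    stop_field("strata$interval_years", "must be positive when screened")
  if (anyDuplicated(s$name))
    stop_field("strata$name", "must be unique")

  if (cfg$n_total < 0) stop_field("n_total", "must be nonnegative")
  if (length(cfg$accrual_counts) !=
      length(cfg$accrual_period_bounds) - 1)
    stop_field("accrual_period_bounds",
               "must have length(accrual_counts) + 1 entries")
  if (any(cfg$accrual_counts < 0))
    stop_field("accrual_counts", "must be nonnegative")
  if (sum(cfg$accrual_counts) != cfg$n_total)
    stop_field("accrual_counts", "must sum to n_total")
  if (any(diff(cfg$accrual_period_bounds) <= 0))
    stop_field("accrual_period_bounds", "must be strictly increasing")
  accrual_end <- cfg$accrual_period_bounds[length(cfg$accrual_period_bounds)]
  if (accrual_end >= cfg$trial_end_years)
    stop_field("accrual_period_bounds",
               "accrual must end before trial_end_years")
  if (cfg$randomization_ratio <= 0 || cfg$randomization_ratio >= 1)
    stop_field("randomization_ratio", "must lie in (0,1)")
  for (f in c("trial_end_years", "prevalence_prob", "sojourn_median_years",
              "noncompliance_sd_months", "annual_arm_interval_years",
              "exit_mammogram_min_enrollment_years")) {
    if (cfg[[f]] <= 0 && f != "prevalence_prob")
      stop_field(f, "must be positive")
  }
  if (cfg$prevalence_prob < 0 || cfg$prevalence_prob >= 1)
    stop_field("prevalence_prob", "must lie in [0,1)")
  if (cfg$prevalence_window_years < 0)
    stop_field("prevalence_window_years", "must be nonnegative")
  if (cfg$last_premammogram_max_years < 0)
    stop_field("last_premammogram_max_years", "must be nonnegative")
  if (cfg$noninferiority_margin <= 0)
    stop_field("noninferiority_margin", "must be positive")
  invisible(cfg)
}

#' Reduced-sensitivity configuration variant
#'
#' Returns a copy of `config` with the per-stratum mammographic sensitivities
#' set to the sensitivity-analysis values (lowest 93%, average 86%, elevated
#' 76%, highest 86%); everything else is unchanged. Applying it twice is a
#' no-op.
#'
#' @param config a `trial_config`.
#' @return a `trial_config`.
#' @export
sensitivity_variant <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  values <- c(lowest = 0.93, average = 0.86, elevated = 0.76, highest = 0.86)
  idx <- match(config$strata$name, names(values))
  if (anyNA(idx))
    stop("sensitivity_variant() requires the default stratum names",
         call. = FALSE)
  config$strata$sensitivity <- unname(values[idx])
  validate_config(config)
  config
}

config_fields <- function() {
  c("n_total", "accrual_counts", "accrual_period_bounds",
    "randomization_ratio", "trial_end_years", "prevalence_mode",
    "prevalence_prob", "prevalence_window_years",
    "sojourn_median_years", "noncompliance_sd_months",
    "annual_arm_interval_years", "exit_mammogram_min_enrollment_years",
    "last_premammogram_max_years", "strata", "noninferiority_margin", "seed")
}

#' Load a configuration from YAML
#'
#' Reads a flat YAML document (a file path or literal YAML text). Unknown
#' keys are rejected; keys left out take their defaults. Strata may be given
#' as a list of mappings with fields `name`, `probability`, `annual_hazard`,
#' `interval_years` (omit or `~` for no screening) and `sensitivity`.
#'
#' @param source path to a YAML file, or a YAML string.
#' @return a validated `trial_config`.
#' @export
load_config <- function(source) {
  doc <- if (length(source) == 1 && !grepl("\n", source) &&
             file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(doc), config_fields())
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(doc$strata)) doc$strata <- strata_from_list(doc$strata)
  do.call(trial_config, doc)
}

strata_from_list <- function(x) {
  if (is.data.frame(x)) return(x)
  rows <- lapply(x, function(r) {
    stratum_spec(
      name = r$name,
      probability = r$probability,
      annual_hazard = r$annual_hazard,
      interval_years = if (is.null(r$interval_years)) NA_real_
                       else r$interval_years,
      sensitivity = if (is.null(r$sensitivity)) 1 else r$sensitivity
    )
  })
  do.call(rbind, rows)
}

#' Serialize a configuration to YAML
#'
#' Writes `config` as a YAML document that [load_config()] reads back
#' field-for-field.
#'
#' @param config a `trial_config`.
#' @param path optional file path; if omitted the YAML text is returned.
#' @return the YAML text, invisibly when written to `path`.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "trial_config"))
  x <- unclass(config)
  x$strata <- lapply(seq_len(nrow(config$strata)), function(i) {
    r <- as.list(config$strata[i, ])
    if (is.na(r$interval_years)) r$interval_years <- NULL
    r
  })
  x <- x[!vapply(x, is.null, logical(1))]
  txt <- yaml::as.yaml(x, precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  n_total: %d women, trial end %.2f y\n",
              x$n_total, x$trial_end_years))
  cat(sprintf("  accrual: %s over bounds [%s]\n",
              paste(x$accrual_counts, collapse = "/"),
              paste(x$accrual_period_bounds, collapse = ", ")))
  prev <- if (x$prevalence_mode == "hazard") {
    sprintf("hazard x %.1f y window", x$prevalence_window_years)
  } else {
    sprintf("uniform %.4f%%", 100 * x$prevalence_prob)
  }
  cat(sprintf("  randomization ratio %.2f, prevalence %s, sojourn median %.2f y\n",
              x$randomization_ratio, prev, x$sojourn_median_years))
  cat(sprintf("  noncompliance sigma %.1f months, first screen offset max %.2f y\n",
              x$noncompliance_sd_months, x$last_premammogram_max_years))
  cat("  strata:\n")
  print(x$strata, row.names = FALSE)
  invisible(x)
}
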