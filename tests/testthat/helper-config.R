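# Scaled-down configurations for fast tests. Accrual counts keep the
# default 5/25/20/15 shape.

small_config <- function(n_total = 2000L, accrual_counts = NULL, ...) {
  if (is.null(accrual_counts)) {
    shape <- c(5, 25, 20, 15) / 65
    accrual_counts <- floor(n_total * shape)
    accrual_counts[1] <- accrual_counts[1] + (n_total - sum(accrual_counts))
  }
  trial_config(n_total = n_total,
               accrual_counts = as.integer(accrual_counts), ...)
}

# Width of a delay matrix wide enough for any schedule under cfg.
max_screens_for_test <- function(cfg) {
  ints <- c(cfg$annual_arm_interval_years, cfg$strata$interval_years)
  as.integer(floor(cfg$trial_end_years / min(ints, na.rm = TRUE))) + 1L
}

# Both arms effectively annual: every stratum screened yearly in the
# personalized arm too, so any departure of P(R<0) from 1/2 is estimator
# artefact, not design.
no_bias_config <- function(n_total = 10000L) {
  s <- default_strata()
  s$interval_years <- 1
  small_config(n_total = n_total, strata = s)
}
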