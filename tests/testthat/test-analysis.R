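# A hand-built trial with known outcomes for exercising the estimators.
toy_trial <- function() {
  cfg <- small_config(8L, accrual_counts = c(2L, 2L, 2L, 2L))
  women <- data.frame(
    id = 1:8,
    entry_time   = c(1.0, 1.0, 0.5, 1.0, 3.0, 1.0, 0.0, 2.0),
    arm          = c("annual", "annual", "annual", "personalized",
                     "personalized", "personalized", "annual",
                     "personalized"),
    stratum      = c(2L, 2L, 2L, 1L, 1L, 1L, 3L, 3L),
    prevalent    = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    t_detectable = c(1.8, 1.0, 9.0, 2.0, 3.5, 9.0, 0.5, 9.0),
    t_clinical   = c(4.4, 2.2, 10, 3.0, 4.0, 10, 1.2, 10),
    interval     = c(1, 1, 1, NA, NA, NA, 1, 1),
    first_planned = c(2, 2, 1.5, NA, NA, NA, 1, 3),
    n_screens_schedule = c(2L, 2L, 3L, 0L, 0L, 0L, 4L, 2L),
    last_screen_time = c(3.1, 3.0, 3.5, NA, NA, NA, 4.0, 4.2),
    exit_time    = c(NA, NA, NA, 4.5, NA, 4.5, NA, NA),
    exit_attended = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                      FALSE),
    n_mammograms = c(2L, 1L, 3L, 0L, 0L, 1L, 1L, 2L),
    detected     = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    mode         = c("clinical", "screen", "none", "clinical", "clinical",
                     "none", "screen", "none"),
    detection_time = c(4.4, 2.0, NA, 3.0, 4.0, NA, 1.0, NA),
    detected_at_first_screen = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                                 TRUE, FALSE),
    prevalent_at_detection = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                               FALSE, FALSE)
  )
  list(td = structure(list(women = women, screens = matrix(NA_real_, 8, 1),
                           trial_end = 4.5), class = "trial_data"),
       cfg = cfg)
}

test_that("total-trial-time exposure runs to detection or trial end", {
  toy <- toy_trial()
  w <- toy$td$women
  exp_tt <- exposure_total_time(w, 4.5)
  expect_equal(exp_tt[3], 4.0)   # undetected: 4.5 - 0.5
  expect_equal(exp_tt[1], 3.4)   # clinical at 4.4, entry 1.0
  expect_equal(exp_tt[2], 1.0)   # screen-detected at 2.0, entry 1.0
})

test_that("complete-cycles censors at the last scheduled screen and drops late events", {
  toy <- toy_trial()
  w <- toy$td$women
  cc <- exposure_complete_cycles(w, 4.5)
  # woman 1: screens at 2.0 and 3.1, clinical detection at 4.4 after the
  # last screen -> event NOT counted, exposure 3.1 - 1.0
  expect_false(cc$event_counted[1])
  expect_equal(cc$exposure[1], 2.1)
  # woman 2: screen-detected at a screen -> counted, exposure to detection
  expect_true(cc$event_counted[2])
  expect_equal(cc$exposure[2], 1.0)
  # woman 4: unscreened personalized with exit mammogram -> included,
  # clinical event at 3.0 counted, exposure 2.0
  expect_true(cc$included[4])
  expect_true(cc$event_counted[4])
  expect_equal(cc$exposure[4], 2.0)
  # woman 5: unscreened personalized, enrolled 1.5 y < 2 y -> excluded
  expect_false(cc$included[5])
  expect_false(cc$event_counted[5])
  expect_equal(cc$exposure[5], 0)
  # woman 6: included non-case, exposure entry -> exit mammogram
  expect_true(cc$included[6])
  expect_equal(cc$exposure[6], 3.5)
  # exposure dominance: never exceeds total-time exposure
  expect_true(all(cc$exposure <= exposure_total_time(w, 4.5) + 1e-12))
})

test_that("hazards, risk differences, and overall combinations are computed", {
  toy <- toy_trial()
  an <- analyze_trial(toy$td, toy$cfg)
  s <- an$summary
  # hazard arithmetic: 100 * events / exposure
  row <- s[s$method == "total_time" & s$stratum == "average" &
             s$arm == "annual", ]
  expect_equal(row$events, 2)
  expect_equal(row$exposure, 3.4 + 1.0 + 4.0)
  expect_equal(row$hazard, 100 * 2 / 8.4)
  # sign convention: R < 0 iff the annual arm has the lower hazard
  r <- an$risk
  r_avg <- r[r$method == "total_time" & r$stratum == "average", ]
  expect_equal(r_avg$risk_difference,
               r_avg$hazard_annual - r_avg$hazard_personalized)
  # elevated stratum: annual 1 event / 4.5 py + personalized 0 events
  r_el <- r[r$method == "total_time" & r$stratum == "elevated", ]
  expect_gt(r_el$risk_difference, 0)
  # pooled overall hazards are sums of events over sums of exposure
  ov <- s[s$method == "total_time" & s$stratum == "overall" &
            s$arm == "annual", ]
  expect_equal(ov$events, 3)
  # average-stratum 8.4 py plus woman 7 (elevated, detected at 1.0)
  expect_equal(ov$hazard, 100 * 3 / (8.4 + 1.0))
  # weighted overall: inverse total-exposure weights over strata
  r_all <- r[r$method == "total_time", ]
  w_s <- 1 / (s$exposure[s$method == "total_time" & s$arm == "annual" &
                           s$stratum != "overall"] +
                s$exposure[s$method == "total_time" &
                             s$arm == "personalized" &
                             s$stratum != "overall"])
  w_s[!is.finite(w_s)] <- 0
  r_s <- r_all$risk_difference[match(toy$cfg$strata$name, r_all$stratum)]
  expect_equal(r_all$risk_difference[r_all$stratum == "overall_weighted"],
               sum(w_s * r_s) / sum(w_s))
})

test_that("a stratum-arm cell with no exposure is flagged degenerate with hazard 0", {
  toy <- toy_trial()
  an <- analyze_trial(toy$td, toy$cfg)
  s <- an$summary
  # highest stratum is empty in this toy trial
  hi <- s[s$stratum == "highest" & s$method == "total_time", ]
  expect_true(all(hi$degenerate))
  expect_true(all(hi$hazard == 0))
})

test_that("toy arithmetic: 2 vs 1 events per 100 py gives R = +1", {
  # direct check of the stated sign convention on constructed hazards
  hazard_annual <- 100 * 2 / 100
  hazard_personalized <- 100 * 1 / 100
  expect_equal(hazard_annual - hazard_personalized, 1.0)
})

test_that("entry-mammogram variant removes prevalent events and adds entry mammograms", {
  toy <- toy_trial()
  v <- apply_entry_mammogram_variant(toy$td)
  expect_true(v$women$event_excluded[2])
  expect_equal(sum(v$women$event_excluded), 1)
  # one extra mammogram per woman on a screening schedule
  extra <- as.integer(!is.na(toy$td$women$interval))
  expect_equal(v$women$n_mammograms, toy$td$women$n_mammograms + extra)

  an <- analyze_trial(toy$td, toy$cfg)
  s <- an$summary
  cc <- s[s$method == "complete_cycles", ]
  em <- s[s$method == "complete_cycles_entry_mammo", ]
  # events drop by exactly the counted prevalent events; exposure unchanged
  expect_equal(em$exposure, cc$exposure)
  # counted prevalent events vanish (stratum and overall rows alike)
  expect_equal(sum(cc$events) - sum(em$events), sum(cc$events_prevalent))
})

test_that("variant equals complete cycles exactly when no cancer is prevalent", {
  cfg <- small_config(3000L, prevalence_mode = "uniform",
                      prevalence_prob = 0)
  td <- run_single_trial(cfg, seed = 14)
  expect_equal(sum(td$women$prevalent), 0)
  an <- analyze_trial(td, cfg)
  cc <- an$summary[an$summary$method == "complete_cycles", -1]
  em <- an$summary[an$summary$method == "complete_cycles_entry_mammo", -1]
  expect_equal(cc$events, em$events)
  expect_equal(cc$exposure, em$exposure)
  # mammogram counts differ only by the synthetic entry mammograms
  expect_true(all(em$n_mammograms >= cc$n_mammograms))
})

test_that("event containment and exposure dominance hold on simulated trials", {
  cfg <- small_config(20000L)
  for (seed in c(101, 202)) {
    td <- run_single_trial(cfg, seed = seed)
    w <- td$women
    tt_exp <- exposure_total_time(w, td$trial_end)
    cc <- exposure_complete_cycles(w, td$trial_end)
    expect_true(all(cc$exposure <= tt_exp + 1e-12))
    # every complete-cycle event is a total-time event
    expect_true(all(w$detected[cc$event_counted]))
    # the events dropped are exactly the clinical detections after the
    # last scheduled screen plus events of excluded women
    dropped <- w$detected & !cc$event_counted
    late_clinical <- w$detected & !is.na(w$interval) &
      w$n_screens_schedule > 0 &
      w$detection_time > w$last_screen_time
    excluded_women <- w$detected & !cc$included
    expect_equal(which(dropped),
                 sort(union(which(late_clinical), which(excluded_women))))
    expect_true(all(w$mode[late_clinical] == "clinical"))
  }
})

test_that("hybrid takes complete cycles for screened strata and total time for the rest", {
  cfg <- small_config(20000L)
  td <- run_single_trial(cfg, seed = 33)
  an <- analyze_trial(td, cfg)
  s <- an$summary
  for (stratum in c("average", "elevated", "highest")) {
    expect_equal(
      s[s$method == "hybrid" & s$stratum == stratum, -1],
      s[s$method == "complete_cycles" & s$stratum == stratum, -1],
      ignore_attr = TRUE)
  }
  expect_equal(s[s$method == "hybrid" & s$stratum == "lowest", -1],
               s[s$method == "total_time" & s$stratum == "lowest", -1],
               ignore_attr = TRUE)
  # overall rows re-pool the mixed per-stratum cells
  hy_ov <- s[s$method == "hybrid" & s$stratum == "overall" &
               s$arm == "annual", ]
  parts <- s[s$method == "hybrid" & s$stratum != "overall" &
               s$arm == "annual", ]
  expect_equal(hy_ov$events, sum(parts$events))
  expect_equal(hy_ov$exposure, sum(parts$exposure))
})

test_that("analysis tables serialize to tidy CSV", {
  toy <- toy_trial()
  an <- analyze_trial(toy$td, toy$cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_analysis(an, path)
  back <- utils::read.csv(path)
  expect_true(all(c("method", "stratum", "arm", "events", "exposure",
                    "hazard", "risk_difference") %in% names(back)))
  expect_equal(nrow(back), nrow(an$summary))
})
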