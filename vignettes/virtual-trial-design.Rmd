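---
title: "Design and conventions of the virtual screening-trial simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and conventions of the virtual screening-trial simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wisdomsim)
```

## The problem

A randomized trial comparing annual mammography with risk-stratified
("personalized") screening over a short horizon cannot use mortality as its
endpoint; it uses the rate of advanced (stage IIB or higher) cancers
instead. That choice makes the comparison exquisitely sensitive to *when*
each arm looks for disease. Without a mandatory entry mammogram, prevalent
cancers surface at each arm's first scheduled screen — earlier in the more
intensively screened arm. Without a mandatory exit mammogram, disease
arising late in the trial is found before trial end more often in the more
intensively screened arm. Either mechanism can make one arm look worse on
the advanced-cancer endpoint when the arms are in truth identical.

`wisdomsim` quantifies these biases by Monte-Carlo: it simulates the whole
trial under a null in which personalized screening neither adds nor removes
disease, applies each candidate analysis rule, and measures how far the
replicate distribution of the between-arm risk difference R strays from
symmetry about zero.

## The simulation model

One virtual trial proceeds in stages, all times in years from trial start.

**Accrual.** `n_total` women (default 65 000) enter uniformly within four
one-year accrual periods holding 5000 / 25 000 / 20 000 / 15 000 women. The
period boundaries are configurable (`accrual_period_bounds`); the four
one-year periods are used because they make the per-arm total-trial-time
exposure come out at roughly 75 000 person-years for a 4.5-year trial,
which is the regime this design targets. Mean entry time is then 2.19 y.

**Randomization.** Each woman is independently assigned to the personalized
arm with probability `randomization_ratio` (default 0.5). Simple
randomization, not a forced split, is deliberate: per-arm counts then vary
binomially between replicates, as they would in a trial that randomizes
individuals as they enroll. A fixed-margin design can be emulated by
post-stratifying, but is not provided.

**Risk strata.** Independently of arm, each woman lands in one of four
strata (lowest / average / elevated / highest) with probabilities 28.9 /
40.4 / 28.2 / 2.5% and annual hazards of mammogram-detectable stage IIB+
cancer of 0.0198 / 0.0414 / 0.0774 / 0.2808% per year. Personalized-arm
screening intervals are none / 2 y / 1 y / 0.5 y respectively; annual-arm
women are screened yearly regardless of stratum. The highest-risk stratum's
semiannual schedule stands in for alternating mammography and MRI; the
simulator treats each visit as one imaging event with the stratum's
sensitivity, so "mammogram counts" for that stratum count combined imaging
events.

**Prevalent disease.** By default (`prevalence_mode = "hazard"`) a woman in
stratum *s* is prevalent with probability
`1 − exp(−annual_hazard_s × prevalence_window_years)` (window default 1 y):
her cancer arose during the year before entry and is still in its
preclinical sojourn. Prevalence therefore tracks risk — the highest-risk
stratum seeds about 2.3 prevalent cancers per arm, the unscreened lowest
stratum about 1.9 — and averages ≈ 0.05% over the default cohort (the
probability-weighted mean of the stratum hazards is 0.0513%). A uniform
mode (`prevalence_mode = "uniform"`, probability `prevalence_prob`) is
available; it seeds the same expected total but allocates prevalence by
cohort share rather than by risk, which changes the stratum-level entry
bias materially (the highest-risk stratum would receive at most 0.4
prevalent cancers per arm and show almost no entry bias). Risk-proportional
prevalence is the default because prevalence of an incidence process *is*
proportional to incidence when sojourn is short relative to follow-up.

**Natural history.** Non-prevalent women draw an exponential time from
entry to mammogram-detectability with their stratum hazard as rate (hazards
are interpreted as rates on the per-year probability scale; at these
magnitudes the rate/probability distinction is below 0.03%). Every woman
draws an exponential sojourn with median `sojourn_median_years` (default
1.5 y, i.e. rate log(2)/1.5), and clinical detectability begins at
detectable time + sojourn. Prevalent women have detectable time equal to
entry; by memorylessness their sojourn draw from entry is the correct
residual sojourn. Onset draws are not truncated at the horizon — most
exceed it — so that observability is decided entirely by the screening
logic.

**Screening schedule.** A woman's first screen is planned
`max(0, interval − t_last)` after entry, where `t_last` is the time since
her last pre-entry mammogram, drawn uniformly on
`[0, last_premammogram_max_years]`. The default for that upper bound is 0:
the first screen is planned one full interval after entry. This is the
convention that makes the simulated per-arm mammogram totals come out at
≈ 42.6 k (annual) and ≈ 26.8 k (personalized) for the default cohort
(≈ 1.3 screens per annual-arm woman); granting up to a year of credit
(`last_premammogram_max_years = 1`) moves first screens earlier and
inflates annual-arm mammograms by roughly 20%. Each screen is delayed by an
independent half-normal noncompliance lag `|N(0, σ)|` with σ = 4 months
(`noncompliance_sd_months`); delays only push screens later, and the next
screen is planned one interval after the *actual* (delayed) visit, so
delays accumulate. σ = 4 gives P(delay < 3 mo) = 0.547 and
P(delay < 6 mo) = 0.866, matching the compliance pattern this population
shows. A screen whose actual time exceeds `trial_end_years` (default
4.5 y) does not happen and ends the schedule. Unscreened personalized-arm
women receive a single exit mammogram at trial end if enrolled at least
`exit_mammogram_min_enrollment_years` (default 2 y).

**Detection.** Mammograms are scanned in time order; a mammogram at time
*s* with `t_detectable ≤ s < t_clinical` detects with probability equal to
the stratum's `sensitivity` (default 1; an independent Bernoulli per
screen, since nothing is known about the correlation of repeated misses of
one lesion). The reduced-sensitivity variant (93 / 86 / 76 / 86% for lowest
→ highest, reflecting the breast-density mix of each stratum) is available
via `sensitivity_variant()`. If no mammogram succeeds and
`t_clinical ≤ trial_end`, the cancer is clinically detected at
`t_clinical`. A woman attends no further mammograms after her detection;
women never detected attend their full schedule.

## The estimators

All four estimators are computed by `analyze_trial()` per stratum × arm,
with hazards per 100 person-years and `R_s = h_annual − h_personalized`.

**Total trial time.** Every woman contributes exposure from entry to
detection or trial end; every detected cancer counts.

**Complete screening cycles.** For women on a schedule, events count only
if detected on or before the woman's *last scheduled screen*, and exposure
runs from entry to detection (counted events) or to that last screen.
The cycle structure is taken from the full realized schedule — the
schedule the woman follows as a non-case — not from the screens she
actually attends: a clinically detected case stops attending screens, but
her detection still falls inside a complete cycle if it precedes the time
her schedule's last screen fell. Without that convention no clinical
detection could ever be counted and the estimator would discard every
interval cancer, which is not what "counting events within complete
cycles" is meant to do. Women with zero completed screens contribute
nothing. Unscreened personalized-arm women are included only if due an
exit mammogram; their single cycle spans entry to that mammogram, so all
their detected events count. Annual-arm women of the lowest stratum follow
the ordinary screened rule.

**Complete cycles + entry mammogram.** As above, but events from women
flagged prevalent are removed in both arms; those women keep their
complete-cycles exposure as non-cases (their events are voided, their
follow-up is not). Reported mammogram counts add one entry mammogram per
scheduled-screening woman. With no prevalent cancers this variant is
identical to complete cycles, a property the test suite checks exactly.

**Hybrid.** Stratum summaries come from complete cycles for the screened
strata and from total trial time for the unscreened stratum, then combine
like any other method.

**Overall combinations.** Two are always reported: *pooled* (sum events
and exposure across strata per arm, difference the pooled hazards) and
*inverse-exposure weighted* (`R = Σ w_s R_s / Σ w_s`,
`w_s = 1/(exposure_s,annual + exposure_s,personalized)`; strata with zero
exposure get weight 0). Pooling reproduces a single-cohort analysis and is
what the per-panel overall rows of the report table print; the weighting
is the appropriate combination when strata are counted under different
exposure rules — in particular for the hybrid, whose strata deliberately
mix accounting conventions, pooling would let the exposure-rich strata
dominate with weights that are artefacts of the accounting choice.

**Degenerate cells.** A stratum × arm cell with zero exposure reports
hazard 0 with a `degenerate` flag and weight 0 in the weighted overall;
at the default cohort size this occurs with negligible probability, and
propagating NaN through replicate aggregation would be worse.

## Replication and aggregation

`run_experiment()` runs independent replicates from a master seed that
spawns one sub-seed per replicate, so results are reproducible and
prefix-stable (replicates 1..k do not depend on how many more follow).
Across replicates it reports means of all counts and exposures, hazards
recomputed as mean events over mean exposure, the mean risk difference,
its 2.5th/97.5th percentile interval, and `P(R < 0)` — the fraction of
replicates with R strictly below zero. Replicates with R exactly zero
count toward neither side and are reported separately (`p_R_eq_0`); in a
no-bias configuration with both arms screened annually, allocating ties
half-and-half leaves the estimate within 0.05 of 0.5, which the test
suite verifies over 1000 replicates. The "95% confidence interval" of the
report table is the percentile interval of the replicate distribution,
not a within-trial interval: the simulator's uncertainty statement is
about the design, not about one dataset.

## Problem sizes used by the tests

The package's own test suite exercises full-size replicates where the
published magnitudes are at stake (800 replicates of 65 000 women for the
operating characteristics; 1000 replicates of a 10 000-woman cohort for
the no-bias symmetry check) and scaled-down cohorts of 500–20 000 women
for structural properties, where cohort size only affects Monte-Carlo
noise. `scripts/acceptance.R` uses 1500 replicates of the full design —
enough to pin probabilities to ±0.013 (one standard error). A vectorized
65 000-woman trial with all four analyses takes on the order of 0.2 s, so
these sizes are comfortable on a single CPU.

## What the generator does and does not emulate

The simulator reproduces the features of the design that create
ascertainment bias: staggered entry, risk-dependent prevalence,
stratum-dependent screening intensity, noncompliance, sojourn-limited
screen detection, and the exit-mammogram rule. It deliberately omits age
structure and risk migration (no woman changes stratum mid-trial), death
and loss to follow-up, benign biopsies and false positives, and any
distinction among cancers below stage IIB. It simulates only the
randomized cohort, not preference-based self-assignment, and it does not
model the risk-assessment machinery (clinical risk models, polygenic
scores, germline panels) that assigns real women to strata. Passing tests
therefore say that the *analysis rules* behave as claimed under this
natural-history null — not that the natural-history model is a faithful
portrait of breast cancer biology; a hazard misspecification would move
absolute event counts but largely cancels in the between-arm comparison,
which is the quantity of interest.

## Numerical and convention choices

* Hazards on the probability scale are used directly as exponential rates
  (error < 0.03% at these magnitudes).
* Stratum probabilities must sum to 1 within 1e-12; at most one stratum
  may be unscreened (zero unscreened strata are allowed so that the
  no-bias "both arms annual" diagnostic is a valid configuration).
* The noninferiority margin (0.05% absolute risk) is carried as a
  configuration constant for completeness; no testing machinery is
  attached to it, since the design's operating characteristics are
  described by the replicate distribution of R rather than by a formal
  test.
* Report tables round only for display; files are written unrounded.
* All per-woman times are absolute (years from trial start), which makes
  the exposure arithmetic subtraction-only and keeps the estimators
  independent of the accrual mechanism.

## Known limitations

Scheduling conventions that real trials leave to clinic calendars (the
first-screen offset, pre-entry mammogram credit, MRI counting) are fixed
here by explicit defaults; aggregate mammogram counts shift by ±10–20%
under reasonable alternatives, and conclusions about mammogram *volume*
should be read with that latitude. The bias probabilities are much less
sensitive, but the highest-risk stratum — 2.5% of the cohort, a few
events per trial — carries wide replicate variability, and its P(R < 0)
should be interpreted on the ±0.02 scale even at 1000 replicates.
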