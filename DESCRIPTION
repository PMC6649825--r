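Package: wisdomsim
Title: Virtual Trial Simulation for Personalized Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microsimulation of a randomized personalized breast cancer
    screening trial (modelled on the WISDOM study design) to quantify
    ascertainment bias introduced at study entry and exit. Simulates
    staggered accrual, risk-stratified exponential natural history with
    exponential sojourn times, screening schedules with half-normal
    noncompliance delays, and screen versus clinical detection. Implements
    the candidate primary-analysis estimators (total trial time, complete
    screening cycles, complete cycles with an entry mammogram, and a
    hybrid), computes per-stratum and overall hazard rates and risk
    differences, and aggregates Monte-Carlo operating characteristics
    (means, percentile intervals, and the probability that the risk
    difference favours the annual arm) across replicate virtual trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
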