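Package: runmech
Title: Running Biomechanics from Treadmill Ground Reaction Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of instrumented-treadmill running from raw ground
    reaction force (GRF) time series. Detects foot-strike, mid-stance and
    toe-off events with a 20 N threshold, computes spatiotemporal variables
    (contact, flight, braking, propulsive and swing times, stride frequency,
    duty factor), per-step kinetics (active and impact vertical peaks,
    braking and propulsive peaks, loading rates, impulses), centre-of-mass
    mechanics by single and double integration of the accelerations from a
    force platform, vertical stiffness, and positive external, internal and
    total mechanical work per kilogram per metre. Includes a synthetic GRF
    generator with an impulse-balanced sine vertical force, biphasic
    fore-aft force, optional early-stance impact transients, noise and
    gradual exhaustion drift, so that every stage of the pipeline can be
    validated against known ground truth, plus study-level summaries
    (impact-peak census, chi-squared tests, Holm adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
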