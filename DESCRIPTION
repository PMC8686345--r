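Package: trialdisrupt
Title: Power Simulation for Pandemic-Disrupted Alzheimer's Disease Trials
Version: 0.1.0
Authors@R: person("ADCS", "Simulation Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the impact of pandemic-style interruptions on the
    statistical power of Alzheimer's disease randomized trials. Generates
    synthetic legacy cohorts with calibrated ADAS-cog change-score
    variability, builds effect-calibrated symptomatic-trial datasets by
    rank-weighted resampling and disease-modification datasets by stratified
    resampling with accrual and pandemic-dropout overlays, applies
    truncation, pause-and-resume, window-extension and remote-assessment
    scenarios, and estimates power under endpoint t tests and mixed models
    for repeated measures with categorical or continuous time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
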