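Package: obesim
Title: Markov Cohort Simulation of Obesity-Related Complications
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time Markov closed-cohort simulation of
    obesity-related complications (type 2 diabetes, acute coronary
    syndrome, stroke, obesity-associated cancers, knee replacement and
    sleep apnea), with prediabetes as an explicit glycemic risk stratum.
    Transition probabilities are supplied by a pluggable registry of
    cardiometabolic risk equations; age- and sex-specific life-table
    mortality is layered with event-year case fatality and post-event
    relative risks. Includes an external-validation workflow that
    compares model-predicted event rates per 1000 patient-years against
    Cox-adjusted observed rates and summarises concordance with a
    zero-intercept least-squares slope and coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
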