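Package: hipscreen
Title: Scenario Simulation for Ultrasound Screening of Developmental Dysplasia of the Hip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-factorial scenario evaluation of implementation strategies for
    general ultrasound screening of developmental dysplasia of the hip (DDH) in
    Dutch infant health care. Enumerates the 72 combinations of machine
    availability, consultation type, screener discipline and location/time,
    simulates synthetic birth cohorts through the screening pathway (attendance,
    reminders, test operating characteristics, itemized societal costs including
    equipment annuities and training), and ranks scenarios by cost per
    screen-detected child, with quartile grouping, level-frequency tables,
    extreme-scenario rankings and one-way sensitivity sweeps. A closed-form
    expected-value engine provides a deterministic counterpart to the
    Monte-Carlo simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
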