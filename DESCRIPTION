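Package: parasitherm
Title: Thermal Ecology of an Insect Host-Parasitoid Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the thermal ecology of insect
    host-parasitoid systems: binomial-logistic dose-response estimation of
    upper lethal temperatures (LT50) with delta-method uncertainty, thermal
    preference statistics from laboratory gradient assays (Brown-Forsythe
    variance tests, paired position tests, preferred-temperature summaries),
    sequential-sum-of-squares analysis of emergence timing, an hourly
    clear-sky microclimate simulator driven by monthly normals, a
    steady-state leaf energy-budget solver, and hour-based thermal risk and
    window-of-opportunity metrics that couple the fitted physiology to
    current and warmed climate scenarios. Includes seeded synthetic-data
    generators emulating heat-shock trials, thermal-gradient assays and
    degree-day development so the full pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    car,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
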