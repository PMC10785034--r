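Package: aqhia
Title: Scenario-Based Air Quality Exposure and Health Impact Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing how anthropogenic emission perturbations
    translate into ambient air quality and premature mortality over a
    gridded domain. Provides a synthetic scenario generator for paired
    business-as-usual and perturbed concentration fields, activity-based
    monthly scaling of sectoral emission inventories with fractional-change
    accounting, regulatory-style ozone (MDA8) and PM2.5 exposure metrics
    with population weighting and emission-versus-meteorology attribution,
    a log-linear concentration-response health impact assessment with
    confidence-interval propagation, and satellite-style tropospheric
    column comparison with model-consistent air-mass-factor recalculation
    and orthogonal distance regression.
License: MIT
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
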