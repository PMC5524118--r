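Package: heartsentinel
Title: Multi-Source Cardiovascular Event Surveillance and Counterfactual
    Baseline Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for national-scale surveillance of acute cardiovascular
    events combined from emergency-department, hospitalization, and death
    registry sources. Builds mutually exclusive event counts from ICD-coded
    records via configurable case definitions and disposition-based exclusion
    cascades, computes stratified and direct age-standardized rates with
    uncertainty, fits inverse-variance-weighted log-linear trend models
    yielding annual percent changes (APCs), projects stable and trend
    counterfactual baselines with Monte Carlo uncertainty propagation, and
    estimates events prevented relative to each baseline with z-score
    inference. Includes a synthetic multi-source data generator with known
    ground-truth trends so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
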