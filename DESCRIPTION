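Package: chwvitals
Title: Validation of Community Health Worker Vital-Events Reporting
Version: 0.1.0
Authors@R:
    person("RMM", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and validation tooling for community-based vital-events
    surveillance. Generates ground-truth birth and under-five death ledgers
    under configurable fertility and age-specific mortality regimes, derives
    community health worker (CHW) monthly reports and retrospective full
    birth/pregnancy history (FBH/FPH) survey datasets through explicit
    observation-error models, and computes completeness, accuracy, data-quality
    and cost metrics over rolling 12-month analysis windows, following standard
    demographic practice (century-month-code dating, period rate ratios, sex
    ratio at birth, age-heaping diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
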