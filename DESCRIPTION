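Package: cowsize
Title: Bioeconomic Modelling of Beef Cow Size in Cow-Calf Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the biological and economic efficiency of beef cows of
    increasing mature body weight in a northern-midwest cow-calf system.
    Provides NRC-style dry-matter-intake and stocking-rate calculations,
    body-condition-score weight normalization and weight-tier classification,
    mixed-model weaning-efficiency regressions with crossed year and cow
    random effects, itemized cow-calf enterprise budgets, and a 10-year
    net-present-value forecaster with a grazing-day sensitivity analysis.
    A synthetic herd generator reproduces the statistical structure of the
    study herd so that every pipeline stage is testable without proprietary
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
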