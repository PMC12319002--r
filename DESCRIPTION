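Package: delphiAHP
Title: Delphi Consensus Statistics and AHP Weighting for Indicator Systems
Version: 0.1.0
Authors@R: person("delphiAHP", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for building weighted evaluation-indicator systems from
    multi-round Delphi expert panels. Computes per-indicator descriptive
    statistics (mean, population SD, coefficient of variation), expert
    authority coefficients, tie-corrected Kendall's W concordance, and
    rule-based indicator screening; derives priority weights with the
    Analytic Hierarchy Process by mapping mean-score differences to Saaty
    pairwise-comparison matrices, checking consistency ratios, and combining
    local weights down a three-level indicator hierarchy. Includes a
    synthetic expert-panel generator so the full two-round pipeline runs and
    is testable without access to raw panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
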