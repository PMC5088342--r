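Package: aecohort
Title: Age-Group Analysis of Adverse-Event Incidence and Diversity in
    Clinical Trial Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parses trial result records in a registry-style XML dialect
    (per-arm enrollment, mean age, and per-event affected/at-risk counts),
    maps adverse-event terms to the 26 MedDRA system organ classes, bins
    trial arms into eight age groups, and computes population-level
    adverse-event statistics across the groups: pooled (micro-average)
    incidence with Wald confidence intervals, risk differences and rate
    ratios against a reference group, Welch t-tests, arm-level adverse-event
    diversity (distinct event types per arm), a 26-by-8 organ-class
    diversity matrix with trial-support masking, within-group competition
    rankings, and per-event cross-group comparisons. A seeded synthetic
    cohort generator with serialized ground truth makes every pipeline
    stage testable without access to a registry download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
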