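Package: pnccoverage
Title: Coverage, Quality Gaps, and Response Consistency for Newborn
    Postnatal Care in Household Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to measure newborn postnatal care from DHS-style
    household survey extracts: derivation of the postnatal-check and
    provider-initiated intervention indicators, a co-coverage index,
    quality-coverage gaps, an internal-consistency classification of
    responses, and pairwise observed agreement, all estimated under a
    stratified two-stage cluster design with Taylor-linearized variance
    and design-based confidence intervals. Includes a synthetic
    generator of DHS-shaped birth-level microdata with known ground
    truth, so the whole pipeline can be exercised and validated without
    access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
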