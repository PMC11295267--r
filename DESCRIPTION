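Package: sihvalid
Title: Validation of Obstetric Hospitalization Claims Against a Reference Census
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating hospital admission-authorization (AIH)
    claims data from Brazil's hospital information system (SIH/SUS) against a
    reference-standard obstetric hospitalization census. Reconstructs episodes
    of care by chaining split admissions on the "continuing inpatient stay"
    billing reason, classifies obstetric hospitalizations, reason for
    hospitalization, discharge type and eleven WHO severe-maternal-morbidity
    criteria from a declarative ICD-10/SIGTAP rulebook, links episodes to the
    reference census with deterministic multi-pass key matching, and computes
    record coverage, sensitivity, specificity and likelihood ratios with the
    interpretation bands used in maternal-morbidity surveillance. Includes a
    synthetic claims generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
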