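Package: crcrisk
Title: Lifestyle and Polygenic Risk Modelling for Colorectal Neoplasm
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing weighted lifestyle scores and polygenic
    risk scores (with Hardy-Weinberg equilibrium quality filtering) from
    case-control colorectal screening data, estimating crude and
    model-adjusted odds ratios for combined risk profiles, projecting
    10-year absolute risk of colorectal neoplasm with attributable-risk
    calibrated baseline hazards and competing non-colorectal mortality,
    and evaluating risk-adapted screening strategies (risk triage to
    colonoscopy or fecal immunochemical test) by positive predictive value
    and number of colonoscopies needed per lesion detected. Includes a
    synthetic cohort generator so the whole chain is testable without
    access to individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
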