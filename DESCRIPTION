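Package: skelevent
Title: Measuring Skeletal-Related Events from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for identifying skeletal-related events (SREs) --
    pathologic fracture, spinal cord compression, bone palliative radiation,
    and bone surgery -- from administrative health-insurance claims in
    patients with metastatic prostate cancer. Provides tiered (high
    specificity / high sensitivity) diagnosis and procedure code lists with
    wildcard matching, composable case definitions, a fracture
    trauma-exclusion rule with a same-level-fall exemption, cohort selection
    with enrollment and censoring logic, clustering of event-days into SRE
    episodes under configurable clean windows, prevalence and cumulative
    incidence tables with cross-configuration comparisons, and a synthetic
    claims generator with known ground truth for validating every pipeline
    stage without access to restricted linked registry-claims data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
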