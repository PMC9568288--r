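Package: implantrisk
Title: Peri-Implant Disease Risk Scoring, Diagnosis and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an additive risk-assessment rubric for peri-implant
    disease. Ten clinical and radiographic parameters (periodontal history and
    compliance, plaque and gingival indices, random blood glucose, smoking,
    residual cement, occlusal overload, keratinized-mucosa width, alcohol) are
    scored per implant, summed to a total risk percentage and categorized as
    low, moderate or high risk. Companion tools classify implants as healthy,
    peri-implant mucositis or peri-implantitis from clinical findings, build
    factor-by-diagnosis contingency tables with Pearson chi-square tests and
    proportions, and generate synthetic implant cohorts, including a
    deterministic 21-implant study fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
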