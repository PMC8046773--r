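Package: teloscore
Title: Genetically Determined Telomere Length Scores and Mendelian
    Randomization for Multiple Myeloma Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds genetically determined telomere-length scores
    ("teloscores") from an 11-SNP instrument panel, performs genotype
    quality control (call rates, duplicate concordance, Hardy-Weinberg
    equilibrium), fits covariate-adjusted logistic models for
    case-control risk and Cox proportional-hazards models for overall
    survival, and runs summary-statistic Mendelian randomization
    (inverse-variance-weighted and MR-Egger regression with Cochran Q
    heterogeneity and the Bowden I2GX instrument-strength statistic).
    Includes a synthetic-cohort generator emulating a multicentre
    myeloma case-control study so the whole pipeline is testable
    without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
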