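Package: braintraj
Title: Normative Regional Brain Volume Trajectories Across Adulthood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building normative references of regional brain volume
    change across adulthood from multi-cohort MRI-derived volumetry.
    Reads FreeSurfer/FastSurfer-style stats files and delimited volume
    tables over the 95-structure Desikan-Killiany-Tourville roster,
    removes sex and cohort confounds by per-region regression
    residualization (with Benjamini-Hochberg verified removal), summarizes
    bilateral volumes over decade age bins, computes symmetric percent-change
    statistics (endpoint, range, maximum consecutive), classifies U-shaped and
    inverted-U trajectories from cubic fits, and quantifies inter-pipeline
    segmentation agreement (ICC, CoV, effect size, reproducibility
    coefficient). Includes a seeded multi-cohort synthetic volume generator
    and a bundled normative table of per-age-bin bilateral means.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
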