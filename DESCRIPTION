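Package: gcpbattery
Title: General Cognitive Performance from Wild Cognitive Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for three-task cognitive test batteries in wild
    animals scored as trials to criterion. Converts trial-level outcomes into
    trials-to-criterion scores with exact chance-level analytics for run-based
    passing criteria, extracts a general cognitive performance (GCP) factor by
    principal component analysis with a within-task permutation null for the
    PC1 loadings, estimates repeatability of GCP across battery replicates,
    ranks mixed-model determinants of GCP by AICc with a top-model-set rule,
    relates GCP to annual reproductive success with Poisson mixed models, and
    computes minimum detectable effect sizes from the noncentral F
    distribution. A synthetic-data generator with known ground truth drives
    calibration and parameter-recovery tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
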