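Package: fairdx
Title: Fairness-Aware Training and Auditing for Image-Based Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing and reducing subgroup bias in binary
    diagnostic classifiers. Implements the marginal pairwise equal
    opportunity metric ("Pairwise Fairness", a subgroup-conditioned
    bipartite-ranking AUC), the pairwise fairness difference (PFD)
    statistic, and a training procedure that per batch selects the
    subgroup with the lowest Pairwise Fairness and minimises a marginal
    ranking loss on it. Ships a synthetic biased-cohort simulator
    (prevalence imbalance, sample-size imbalance, class-separability
    disparity), patient-level repeated splits, a chest X-ray style
    preprocessing chain, and an experiment driver that compares the
    fairness-aware loss against cross-entropy and minority-oversampling
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
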