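Package: flowccr
Title: Multi-Profile Detection of B-Cell Lymphoma from Flow Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated immunophenotyping of B-cell lymphoproliferative
    disorders from flow cytometry event data. Five markers (kappa, lambda,
    CD19, CD5, CD10) are collapsed into a three-dimensional space in which
    healthy, chronic lymphocytic leukemia (CLL), and follicular lymphoma (FL)
    cohorts are summarised as Gaussian-mixture ellipsoid profiles. Test cases
    are matched to each profile by T-cell-anchored rigid alignment, scored by
    the B-cell capture rate (CCR), and diagnosed by nearest-axis distance in
    CCR space. Includes doublet removal, automated lymphocyte gating, a
    synthetic cohort generator with ground-truth labels, and cross-validation
    and training-case selection experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
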