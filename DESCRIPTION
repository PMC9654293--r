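Package: l3compo
Title: Body-Composition Analysis of Single-Slice Abdominal CT at L3
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies fat and muscle compartments on a single axial CT
    slice at the level of the third lumbar vertebra by Hounsfield-unit
    banding (subcutaneous, visceral and intermuscular fat; five muscle
    radiodensity bands), normalizes areas by squared height, gates
    duplicate-rater measurements by Spearman reliability, and computes
    follow-up changes. A cohort layer provides the statistical battery used
    in clinical body-composition studies: normality-routed group
    comparisons, Spearman correlation matrices, median-dichotomized
    coincidence networks weighted by adjusted standardized (Haberman)
    residuals, and confounder-adjusted logistic regression of mortality.
    Synthetic CT phantoms with analytically known compartment areas and
    synthetic cohorts with planted outcome effects provide ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
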