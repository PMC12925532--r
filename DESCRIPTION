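Package: aneumorph
Title: Three-Dimensional Morphometry of Intracranial Aneurysm Segmentations
    and Sex-Difference Analysis
Version: 0.1.0
Authors@R:
    person("Aneumorph", "Developers", email = "aneumorph@example.org",
           role = c("aut", "cre"))
Description: Quantifies the three-dimensional morphology of binary aneurysm
    segmentations (volume, surface area, sphericity, elongation, flatness,
    Koenderink shape index and curvedness) via iso-surface meshing of the
    voxel mask, and compares morphology between women and men with a
    transformation / multiple-imputation / regression pipeline (natural-log
    and Box-Cox transforms, Z-standardization, median dichotomization,
    linear and logistic models, Rubin's-rules pooling, noncentral-F sample
    size calculation). Includes synthetic voxel phantoms with analytically
    known morphology and a patient-cohort simulator with configurable sex
    effects and missing smoking data, so the whole pipeline is testable
    against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
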