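Package: brainergetics
Title: Regional Brain Energetics Pattern Analysis from PET/MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the regional organization of brain energy
    metabolism from simultaneous FDG-PET and arterial-spin-labelling MRI.
    Converts regional cerebral metabolic rate of glucose (CMRglu) and
    cerebral blood flow (CBF) into relative energy production (rEP) and
    relative aerobic glycolysis (rAG) via per-subject z-scoring and a 45
    degree rotation; derives cross-validated age-related spatial covariance
    patterns with Scaled Subprofile Model PCA (SSM-PCA) and logistic
    recombination; validates them with Partial Least Squares Correlation
    (PLSC); and scores subjects against externally supplied disease-related
    metabolic patterns with a regionalized Topographic Profile Rating (TPR).
    Includes Patlak graphical quantification of FDG net uptake, regional
    aggregation of parametric volumes, and a synthetic cohort generator with
    the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    deSolve,
    pracma,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
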