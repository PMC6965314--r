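Package: gfconn
Title: Voxel-Wise Global-Brain Functional Connectivity Analysis for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for voxel-wise global-brain functional
    connectivity (GFC) analysis of resting-state fMRI: per-subject
    preprocessing (initial-volume discard, Gaussian smoothing, linear
    detrending, band-pass filtering, Friston-24 plus white-matter and
    cerebrospinal-fluid nuisance regression, framewise-displacement
    scrubbing), per-voxel mean correlation with all other gray-matter
    voxels (Fisher z), covariate-adjusted voxel-wise group inference with
    permutation-based family-wise error control, cluster extraction and
    clinical-score correlation, and support-vector-machine patient/control
    discrimination with leave-one-out, k-fold and permutation validation.
    Includes a seeded synthetic-cohort generator that plants known
    connectivity effects so the whole chain is testable without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
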