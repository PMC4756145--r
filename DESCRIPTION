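Package: netconsist
Title: Consistency of Subcortical-Cortical Intrinsic Connectivity Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying how consistently
    subcortical-cerebellar-to-cortical intrinsic functional connectivity
    patterns differ between two groups of resting-state fMRI subjects.
    Stages: seeded synthetic BOLD cohort simulation with planted
    ROI-to-network coupling shifts, motion/tSNR quality control and
    band-pass/nuisance temporal preprocessing, group spatial ICA (two-step
    PCA, infomax, multi-run ICASSO stability, dual-regression
    back-reconstruction, template matching), four families of Fisher-z
    connectivity feature matrices, linear support-vector-machine
    classification with leave-one-out cross-validation, and an exact paired
    binomial test comparing the per-subject classification outcomes of
    feature families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
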