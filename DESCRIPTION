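Package: somatopipe
Title: Simulation and Analysis of Block-Design fMRI of Adjacent Somatosensory Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-subject block-design fMRI of small, adjacent
    somatosensory relay nuclei (cuneate and spinal trigeminal nuclei in the
    brainstem, ventroposterior thalamus, primary somatosensory cortex) and
    analyses the simulated data end to end: physiological (RETROICOR-style)
    nuisance regressors, first-level voxelwise GLM with a canonical
    double-gamma haemodynamic response and its temporal and dispersion
    derivatives, fixed-effects combination across runs, ROI statistics with
    repeated-measures or Friedman tests, nonparametric sign-flip group
    inference with threshold-free cluster enhancement, and across-participant
    multiclass linear SVM decoding with leave-one-subject-out
    cross-validation, permutation inference, and searchlight mapping with
    permutation cluster-size correction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
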