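Package: popcode
Title: Simulation and Searchlight Decoding of Population-Code Sharpening in fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing event-related fMRI experiments in
    which expectations generated during action modulate visual population codes.
    A synthetic-data generator instantiates competing sharpening, cancellation
    and null hypotheses about how expectation changes voxel responses, either as
    run-wise beta images or as HRF-convolved BOLD time series. The analysis
    pipeline mirrors a standard multivariate decoding workflow: first-level GLM
    estimation, linear-SVM searchlight decoding of observed-stimulus identity
    with leave-one-run-out cross-validation, group cluster inference with a
    height threshold and a sign-flip permutation extent threshold to define
    regions of interest, repeated-measures ANOVAs on cluster-mean decoding
    accuracies, and a voxel-tuning analysis that tests whether congruency
    effects on univariate signal are confined to voxels tuned towards or away
    from the expected stimulus. A model-recovery experiment quantifies how well
    the pipeline discriminates the competing hypotheses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
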