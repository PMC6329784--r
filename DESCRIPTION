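Package: roughmvpa
Title: Searchlight Decoding of Tactile Roughness Intensities from Multivoxel
    fMRI Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end multivoxel pattern analysis of perceived tactile
    roughness intensity. Generates synthetic fMRI volumes and
    magnitude-estimation ratings with known ground truth, estimates
    trial-wise response amplitudes by ordinary least squares against
    box-car regressors convolved with a canonical double-gamma
    hemodynamic response (discrete-cosine high-pass drift model),
    decodes five roughness intensities with a pooled-variance Gaussian
    Naive Bayes classifier inside a moving 3x3x3 voxel searchlight under
    run-wise and cross-modal cross-validation, performs random-effects
    group inference with cluster-extent correction calibrated by
    sign-flip permutation, and relates per-cluster confusion matrices to
    behaviorally derived similarity via Mantel permutation tests and
    nonmetric multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Matrix,
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
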