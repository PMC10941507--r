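Package: connectograd
Title: Functional and Structural Connectome Gradients with KL-Divergence
    Morphometric Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-level functional (Fisher-Z Pearson) and
    structural (symmetric Kullback-Leibler divergence of vertex surface-area
    densities) connectomes from parcellated brain data, embeds them into
    low-dimensional gradient components by diffusion maps on a sparsified
    cosine-affinity matrix, aligns components across individuals by iterative
    Procrustes rotation, and runs the downstream group analyses: gradient
    span, ROI- and network-level comparisons with false-discovery-rate
    control, support-vector-machine classification of network gradient
    features with ROC/AUC evaluation, and covariate-controlled correlation
    between gradient change and clinical motor-score change. Includes a
    synthetic cohort generator that plants a sensorimotor-to-association
    correlation axis, group span effects, network-dependent vertex-area
    shifts, and a treatment-restoration signal, so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
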