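Package: mrcpgrasp
Title: Decoding Reach-and-Grasp Movements from Movement-Related Cortical Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-trial decoding of reach-and-grasp movements from
    low-frequency electroencephalography (EEG). Implements a paradigm-faithful
    synthetic EEG generator (movement-related cortical potential templates,
    1/f background noise, ocular and burst artifacts, button/force channels),
    BrainVision-format input/output, deterministic signal conditioning
    (channel selection, zero-phase Butterworth filtering, common average
    reference, downsampling), trial- and component-level artifact rejection
    (reaction-time screening, amplitude thresholding, joint-probability and
    kurtosis outliers, ICA-based ocular cleanup), behavioral timing analysis
    with repeated-measures ANOVA, grand-average MRCP statistics with
    sample-wise Wilcoxon rank-sum testing, and sliding-window
    shrinkage-regularized linear discriminant decoding with one-vs-one
    multiclass voting, repeated stratified cross-validation, confusion
    matrices and adjusted-Wald chance bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
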