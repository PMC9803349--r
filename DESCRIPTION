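Package: spinescope
Title: Spine-Resolved Two-Photon Calcium Signal Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of dendritic spine calcium signals from longitudinal
    two-photon imaging. Converts raw ROI fluorescence to drift-corrected
    dF/F, isolates spine-specific signals by robust (bisquare IRLS)
    subtraction of the paired dendritic signal, detects supra-threshold
    calcium events and computes amplitude, frequency and integral metrics,
    classifies spines as sensory-responsive, network-correlated or
    unclassified using binarized-stimulus correlations, a dummy-stimulus
    false-positive threshold and a leave-one-out network signal, and runs
    longitudinal homeostasis analyses (inactive/persistent tracking,
    baseline-normalized changes, dendritic clustering with a shuffle null,
    global dendritic response correlations). Includes a synthetic-data
    generator with known ground truth emulating awake-mouse recordings
    under visual and auditory stimulation and sensory-deprivation
    paradigms, so that every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
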