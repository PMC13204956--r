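Package: mscascade
Title: Multi-Band EEG Microstate Fusion and Two-Stage Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for continuous multi-band EEG microstate analysis and
    subject-level dementia classification. Extracts microstate templates from
    global field power peaks with a polarity-invariant modified k-means,
    aligns narrowband templates to broadband anchors by minimum-cost bipartite
    (Hungarian) matching, and backfits continuous soft-assignment correlation
    trajectories that are fused across frequency bands. Fused sequences feed a
    normalizer-free 1D convolutional network with multi-head self-attention,
    trained with adaptive gradient clipping and weighted cross-entropy under a
    leakage-free leave-one-subject-out protocol with subject-level majority
    voting. Includes a two-stage screening/subtyping cascade, attention-based
    interpretability scores, evaluation statistics (exact McNemar, Friedman,
    Mann-Whitney U, Benjamini-Hochberg correction), minimal EDF and BrainVision
    readers/writers, and a class-conditional synthetic EEG generator with
    planted microstate ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'montage.R'
    'io-edf.R'
    'io-brainvision.R'
    'io.R'
    'preprocess.R'
    'hungarian.R'
    'microstate.R'
    'synthetic.R'
    'nn-layers.R'
    'nfnet.R'
    'stats.R'
    'pipeline.R'
    'cascade.R'
    'plots.R'
    'mscascade-package.R'
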