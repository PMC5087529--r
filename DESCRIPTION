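Package: ecgmdfx
Title: Multi-Domain Feature Extraction and Classification of ECG Heartbeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for automatic recognition of five classes of
    ECG heartbeats (normal, left and right bundle branch block, premature
    ventricular contraction, atrial premature beat). Pre-processing uses a
    five-level sym6 discrete wavelet transform with an improved threshold
    function that blends soft-style shrinkage with asymptotic identity.
    Nonlinear features are extracted by PCA followed by kernel independent
    component analysis (kernel canonical-correlation contrast) and projection
    of beats onto the recovered base-signal subspace; frequency-domain
    features come from four-level db2 wavelet band statistics reduced by
    Fisher linear discriminant analysis. Classification uses an RBF support
    vector machine whose penalty and kernel width are tuned by a binary-coded
    genetic algorithm with cross-validated fitness. Includes a synthetic
    five-class beat generator with white-noise and power-line interference,
    readers for WFDB and CSV ECG records, beat segmentation, evaluation
    metrics (sensitivity, specificity, positive predictivity, accuracy), and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
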