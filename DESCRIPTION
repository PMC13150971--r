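Package: lungfuse
Title: Heuristic Lung-Field Priors and Early-Fusion Segmentation for Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Training-free extraction of structural lung-field priors from
    posteroanterior chest radiographs (adaptive Laplacian-of-Gaussian and dual
    Canny edge channels, morphological-reconstruction pruning, spine modelling
    and removal, and a heuristic predicted lung mask), together with an
    early-fusion front end (binary channel selection and a learnable 1x1
    channel mixer) and a compact encoder-decoder training and evaluation
    harness supporting hold-out, k-fold and cross-dataset protocols. Includes
    a seeded synthetic chest-radiograph phantom generator with paired ground
    truth for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), tiff, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
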