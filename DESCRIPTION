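Package: molviews
Title: Multi-View 3D Molecular Representation Learning and Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns multimodal small-molecule representations by fusing 1D
    fingerprints, 2D molecular-graph embeddings and 3D spatial visual features
    obtained from six orthogonal ball-and-stick renderings of an
    MMFF94s-minimized conformer. A direction-aware 3D convolutional
    autoencoder encodes the rendered views, a self-controlled gated residual
    network (SCRN) fuses the three modalities, and a symmetric-normalized
    graph convolutional network scores drug-target, drug-drug and drug-miRNA
    links; a feed-forward head supports scalar endpoint regression.
    Includes deterministic orthographic rendering, Bemis-Murcko scaffold
    splitting, orphan-entity evaluation, Grad-CAM interpretability, and a
    synthetic-fixture generator with planted, Bayes-bounded interaction
    graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ChemmineOB,
    Biostrings,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
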