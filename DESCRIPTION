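Package: caprid
Title: Multi-View Individual Identification for Livestock Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for identifying individual animals from multi-view
    appearance images: perceptual-hash (dHash) and structural-similarity
    (SSIM) near-duplicate frame removal, balanced dataset construction
    with augmentation, per-view softmax identity classifiers,
    accuracy-weighted decision-level fusion of view confidences,
    confidence-threshold acquisition policies (single-camera voting and
    multi-camera cascades), and a synthetic multi-view herd generator so
    the whole pipeline can be exercised end to end without animal image
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
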