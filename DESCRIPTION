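Package: lungprompt
Title: Text-Prompt-Guided Lung Field Segmentation with Verifiable Oracle Backends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A testable implementation of a text-prompt-guided chest
    radiograph segmentation pipeline: Otsu binarization preprocessing,
    word-level anatomical prompt construction, confidence-thresholded
    prompt-based detection, iterative bounding-box refinement by greedy
    local search, overlap metrics (IoU, binarized-predicted IoU, soft Dice
    loss, stability score), and reliability-diagram calibration. Ships a
    synthetic chest-phantom generator with exact per-lobe ground-truth
    masks plus deterministic oracle detector and segmenter backends, so
    every pipeline stage is verifiable without pre-trained model weights;
    real zero-shot detector/segmenter models can be plugged in behind the
    same contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
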