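Package: pestfuse
Title: Multi-Image Pest Recognition by Feature Localization and Gated Attention Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for fine-grained pest image classification
    from groups of same-class images. A small convolutional backbone exposes
    every block of its last stage; an activation-map localization module
    thresholds channel-summed activations with an epoch-scheduled multiplier,
    intersects per-block masks and crops the shared bounding box; a gated
    multi-head self-attention module fuses the group's embeddings under
    learned sigmoid query/key masks and a hard selection mask; a shared
    classifier with soft voting integrates the per-image probabilities into
    one decision. Includes a synthetic dataset generator that emulates
    cluttered backgrounds, label errors, target-absent frames and blur, a
    two-branch training loop with jointly optimized cross-entropy losses, and
    accuracy / weighted F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
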