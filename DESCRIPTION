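Package: derm2macro
Title: Adversarial Dermoscopic-to-Macroscopic Translation for Skin Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for augmenting scarce macroscopic (clinical, mobile-acquired)
    skin lesion images with the much larger pool of dermoscopic images. Provides
    an unpaired two-domain adversarial image translator with cycle-consistency
    loss, a reduced MobileNetV2/DeepLab-style encoder-decoder lesion segmenter
    trained with a soft Dice loss, and an evaluation stack: Frechet distance
    between embedded image sets, the Variation Ratio, and the thresholded
    Jaccard metric suite used in skin lesion segmentation challenges. A built-in
    synthetic two-domain lesion image generator (pigment-network texture, dark
    corners, gel and ruler artifacts for the dermoscopic domain; glare and depth
    shading for the macroscopic domain) makes the whole pipeline testable
    without access to restricted clinical databases. All networks run on a small
    self-contained CPU convolution engine with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
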