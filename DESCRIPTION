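Package: feccnet
Title: Lightweight Dual-Encoder Segmentation of Stroke Lesions in Brain MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements FECC-Net, a lightweight encoder-decoder convolutional
    network for binary segmentation of chronic-stroke lesions in axial T1 MRI
    slices. The network combines a four-level main encoder with
    squeeze-and-excitation channel attention, atrous spatial pyramid pooling at
    the bottleneck, and a secondary "enhanced" encoder built from depthwise
    separable convolutions that feeds boundary-rich shallow features to the
    decoder through additional skip connections. Training minimises a hybrid
    loss, the L2 combination of binary cross-entropy and Dice loss. The full
    forward and backward passes and the Adam optimiser are implemented on base
    R matrix algebra, so the package runs on CPU with no external deep-learning
    framework. Ships a seeded synthetic lesion-slice generator, NIfTI slice
    extraction, lesion-size-stratified evaluation (Dice, mean IoU, recall,
    precision) and a Gaussian-noise robustness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
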