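Package: vssunet
Title: Multiscale Visual State-Space U-Net for Pest Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A U-shaped encoder-decoder semantic segmentation network built
    from multiscale visual state-space (Mamba-style selective-scan) blocks,
    with channel-spatial attention-gated skip connections and an
    attention-refined state-space bottleneck, trained with a hybrid
    Dice plus cross-entropy loss. Includes the four-direction 2D selective
    scan (SS2D) with a sequential reference recurrence, analytic
    complexity accounting, stratified segmentation evaluation by pest size
    and image entropy, a synthetic paddy pest-scene generator with exact
    ground-truth masks, the field augmentation protocol, k-fold splitting,
    and SGD training of the full model on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
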