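Package: vertebox
Title: Vertebra CT Segmentation with a Dual-Attention Multi-Scale
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Verte-Box encoder-decoder convolutional network
    for segmenting vertebrae in axial computed-tomography slices: channel and
    position attention gates on the skip and bottleneck features, Res2Net-style
    multi-scale convolution blocks with a layer-wise scale schedule, and a
    "feature box" of deeply supervised coarse prediction heads fused into the
    final segmentation. Includes the full training protocol (AdamW,
    reduce-on-plateau learning-rate schedule, Dice-based deep supervision
    loss), CT preprocessing (isotropic resampling, axial slicing, intensity
    windowing, augmentation), evaluation metrics (Dice similarity coefficient,
    intersection over union, 95th-percentile Hausdorff distance, paired
    comparisons), and a parametric vertebra phantom generator for
    download-free testing and training. All network forward and backward
    passes are implemented in R with C++ convolution kernels; no external
    deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
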