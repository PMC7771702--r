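Package: skullmark
Title: Two-Stage Localization of Bregma and Lambda in Rodent Skull Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates the bregma and lambda skull landmarks in photographs of
    rodent skulls with a two-stage pipeline: a region-of-interest stage that
    detects the skull in a downsampled image and extracts a fixed-size
    full-resolution crop, and a refinement stage that regresses truncated
    Gaussian landmark heatmaps with a fully convolutional encoder-decoder
    built from bottleneck residual blocks, decoding coordinates by
    per-channel argmax.  Includes a seeded synthetic skull-scene generator
    with exact analytic ground truth, label-consistent flip/rotate/shift
    augmentation, cross-validation manifests, and localization-error
    evaluation in pixels and micrometres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
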