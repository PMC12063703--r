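Package: vpsfda
Title: Source-Free Domain Adaptation of 2-D Segmentation Models with Input-Specific Visual Prompts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage source-free unsupervised domain adaptation for 2-D
    medical image segmentation. Stage one trains an input-specific visual
    prompt generator (a double-branch alignment model built from modulated and
    demodulated convolutions) by matching the batch statistics of prompted
    target images to the batch-normalization running statistics frozen inside
    a pretrained source model. Stage two self-trains a copy of the source
    model on the prompted images using confidence-masked cross-entropy against
    double-threshold-denoised pseudo-labels. Includes Dice and average surface
    distance metrics, an input-agnostic prompt baseline, a plug-in denoiser
    interface, and a seeded synthetic cross-modality phantom generator so the
    whole pipeline runs at desk scale on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    RNifti,
    yaml,
    jsonlite,
    tibble,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
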