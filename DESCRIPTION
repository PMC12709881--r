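Package: kernelCT
Title: Micro-CT Segmentation and Phenotyping of Maize Kernel Endosperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A micro-computed-tomography image analysis toolkit for the internal
    structure of maize kernels. Provides batch-scan kernel extraction (Canny
    edge based), an attention-augmented U-Net segmenter (CBAM blocks in the
    encoder, squeeze-and-excitation blocks in the decoder) for separating
    vitreous from starchy endosperm, a composite focal-Tversky plus
    boundary-smoothing training objective, mask-based 3D phenotype extraction
    (volumes, volume ratios, bounding-box dimensions), and a deterministic
    synthetic phantom generator so the whole pipeline is testable end to end
    without scanner data. Slice stacks are read from 8-bit BMP or PNG series
    and label volumes from NIfTI-1 or indexed PNG stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    Rcpp,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
LinkingTo:
    Rcpp,
    RcppArmadillo
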