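Package: vesselseg
Title: Hybrid Expert-System and Convolutional Segmentation of the
    Abdominal Vascular Tree from CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic segmentation of the abdominal vascular tree
    (arterial lumen, intraluminal thrombus, and the adjacent spine) from
    contrast-enhanced CT angiography volumes.  Combines a rule-based
    expert system (Hounsfield-unit windowing, boundary propagation and
    morphological active contours without edges) with symmetric
    convolutional encoder-decoder networks trained on labels produced by
    the expert system itself.  Includes a synthetic abdominal CTA phantom
    generator with ground-truth masks, a full evaluation-metric suite
    (Dice, Jaccard, sensitivity, specificity, volume similarity,
    Hausdorff distance) with paired method comparison, reading and
    writing of DICOM series and NIfTI volumes, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
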