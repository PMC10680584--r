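Package: unseg
Title: Unsupervised Segmentation of Cells and Nuclei in Two-Channel Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unsupervised instance segmentation of cells and their nuclei in
    two-channel fluorescence images of tissue (one nucleus marker such as
    Hoechst or DRAQ5, one cell-membrane marker such as Na+K+ATPase). Per-pixel
    a-priori probabilities derived from intensity distribution functions are
    fused with a contrast-based likelihood into posterior semantic masks
    (background / nucleus / membrane), which are then parsed into nucleus
    instances via convexity analysis, a perturbed-watershed cluster splitter
    and virtual cuts, and into cell instances via membrane-constrained
    expansion of each nucleus. Includes a synthetic tissue-image generator
    with exact ground truth, F1-versus-IoU evaluation utilities, and label
    TIFF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
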