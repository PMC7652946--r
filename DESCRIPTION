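Package: texrob
Title: Inter-Reader Robustness of CT Texture Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how inter-reader lesion contouring variability
    propagates into grey level co-occurrence (GLCM) and grey level run
    length (GLRLM) texture features of contrast-enhanced CT liver lesions.
    Provides a synthetic textured-lesion phantom generator with two
    simulated readers, NIfTI volume and binary labelmap input/output,
    derivation of 3D, largest-axial-slice 2D, and circular regions of
    interest, fixed-range intensity discretization with IBSI-style
    feature formulas, contour agreement metrics (Dice coefficient,
    average Hausdorff distance), and per-feature robustness statistics
    (mean relative change, single-rater two-way random-effects
    intraclass correlation) with the companion analyses (Wilcoxon
    signed-rank, Spearman correlation, size-versus-agreement regression,
    circular-ROI comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
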