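Package: radiorobust
Title: Robustness of 3D Radiomic Features to Segmentation and Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of IBSI-style radiomic features (shape, first-order,
    GLCM, GLRLM, GLSZM, NGTDM, GLDM; original and coif1 wavelet sub-band
    images, 851 features in total) from 3D grayscale volumes with binary
    lesion masks, and quantification of their robustness to segmentation
    variability. Per-feature agreement across segmentation styles is scored
    by the two-way random-effects, absolute-agreement, single-measure
    intraclass correlation coefficient (ICC) with an F-based 95% confidence
    interval; sensitivity of the ICC to gray-level bin width, texture pixel
    distance, interpolator and isotropic resampling resolution is summarised
    as the worst-case range over a full factorial preprocessing grid; the
    per-patient coefficient of variation across segmentations is correlated
    with lesion volume by Spearman rank correlation. A synthetic CT-like
    phantom-cohort generator with three segmentation styles per lesion
    (accurate free-hand, rough free-hand, rough polygonal) makes the whole
    pipeline runnable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    igraph
Config/testthat/edition: 3
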