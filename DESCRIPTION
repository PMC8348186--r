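Package: brulat
Title: Latent Bruise Detection in Apples from SWIR Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting latent (sub-visible) bruise
    damage in apples from short-wave infrared (930-2500 nm) hyperspectral
    images. Provides a synthetic hypercube generator emulating a controlled
    drop-impact bruising experiment with six severity levels and five scan
    times; ENVI-format hypercube input/output with unfold/fold between cube
    and pixel-matrix views; automated PCA-based background removal;
    hyperspectrogram dimensionality reduction (PCA loadings concatenated with
    distribution curves of per-pixel scores, Q residuals and Hotelling T2);
    bruise visualisation by principal-component score images; region-of-
    interest mean-spectrum extraction with severity/time class coding; and a
    battery of four classifiers (quadratic-kernel SVM, 1-nearest-neighbour,
    regularised linear discriminant, and a random-subspace discriminant
    ensemble) with stratified 10-fold cross-validation, AUC, confusion-matrix
    and prediction-speed evaluation, orchestrated into detection, temporal
    and quantitative severity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    class,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
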