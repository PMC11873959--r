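Package: lilac
Title: Pairwise Comparison Learning for Longitudinal Image Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies and localizes relevant temporal change in
    longitudinal image sequences by learning to compare pairs of images
    from the same subject (the LILAC approach). A shared four-block
    convolutional feature extractor feeds a bias-free linear head applied
    to the difference of the two feature vectors, optionally concatenated
    with per-timepoint metadata; task variants cover temporal ordering,
    time-interval prediction and metadata-controlled target-change
    prediction, alongside a single-image regression baseline. Includes
    element-wise gradient-based saliency maps with explainability-score
    gating and population peak summaries, bootstrap AUC evaluation,
    ordered-pair Pearson correlation, a no-intercept random-slope linear
    mixed-effects slope analysis with likelihood-ratio tests, and a
    synthetic longitudinal cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    png,
    Rcpp,
    RNifti,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
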