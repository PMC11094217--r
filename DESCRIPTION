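Package: hossnf
Title: Heap-Optimizer Segmentation and Neuro-Fuzzy Classification of
    Single-Cell Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying single-cell Pap-smear
    images into seven cytological classes. Cell images are denoised
    (median filter, wavelet shrinkage), segmented into background,
    cytoplasm and nucleus by multilevel thresholding driven by a
    heap-based population optimizer with Kapur-entropy or Otsu
    objectives, described by GLCM, local-binary-pattern and Gabor-bank
    texture features, and classified by a six-layer self-systematized
    neural fuzzy network (Gaussian antecedents, TSK-style linear
    consequents) whose parameters are fitted by the same optimizer.
    Includes a synthetic phantom generator with ground-truth masks,
    confusion-matrix evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
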