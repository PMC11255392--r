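Package: lumicell
Title: Population Calcium-Imaging Analysis of Luminance Responses in the
    Larval Zebrafish Cerebellum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing two-photon population calcium imaging
    of luminance-evoked activity in cerebellar granule cells, inferior olive
    neurons and Purkinje cells: piecewise-constant luminance protocols and a
    kernel-convolved regressor bank; plane-wise rigid motion correction,
    neighbour-correlation maps and seeded ROI growing; trial-reliability
    gating with Otsu thresholding; Ward clustering of mean responses;
    regressor classification and cross-validated center-of-mass timing;
    ridge and support-vector decoding of time and luminance from population
    vectors; a bounded nonnegative L1-regularised model attributing Purkinje
    activity to granule-cell and inferior-olive cluster regressors with a
    shuffle null; swim-bout detection with a bootstrap test for post-offset
    suppression; and seeded synthetic-data generators with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
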