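Package: hcscreen
Title: High-Content Reporter Screen Analysis with Robust SSMD Hit Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for 384-well fluorescence-reporter high-content
    screens of the kind used to find small-molecule enhancers of a promoter
    reporter in differentiating myotubes. Implements the image-quantification
    chain (grayscale top-hat background removal, adaptive thresholding with
    width and intensity constraints, minimum-area filtering, per-well
    fluorescence quantification and artifact flagging), robust SSMD*-based
    plate quality control and two-stage hit calling, plate normalization,
    pipetting/dilution arithmetic, ddCT relative quantification of qPCR data,
    fusion-index morphometrics, densitometry normalization, viability and
    dose-response summaries, and a synthetic-data generator that emulates
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
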