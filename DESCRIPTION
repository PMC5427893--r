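Package: vesselfract
Title: Vascular Network Morphometry, Fractal Complexity and MR Lesion
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 2D images of labeled cerebrovascular networks with
    classical skeleton morphometry (junction counts, total vessel length,
    vessel density), maps local connected fractal dimension by sliding-box
    counting and summarizes its histogram (peak value, peak frequency,
    skewness, kurtosis), builds concentric-ring and hemispheric analysis
    regions around an injury epicenter, and segments MR volumes by
    hierarchical region splitting with susceptibility-weighted phase-mask
    processing. Ships a seeded synthetic vessel-network and MR-phantom
    generator with exact ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    RNifti,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
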