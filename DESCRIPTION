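Package: octalesion
Title: Automatic Skin Lesion Area Determination from OCT Angiography
Version: 0.1.0
Authors@R:
    person("octalesion", "developers", email = "octalesion@example.org",
           role = c("aut", "cre"))
Description: Quantifies cutaneous microvasculature in optical coherence
    tomography angiography (OCTA) volumes and automatically delineates basal
    cell carcinoma (BCC) lesion areas. Implements vessel enhancement (3D median
    filtering and multiscale Frangi vesselness), slice-wise fast adaptive
    thresholding, topology-preserving 3D skeletonization with graph
    decomposition, seven quantitative vascular parameters (number of trees and
    branches, vascular density, mean radius, distance metric, inflection count
    metric, sum of angles metric), overlapping region-of-interest vascular
    density heat maps, and a rule-based detector that flags lesion presence,
    discriminates superficial from nodular BCC, extracts the lesion area, and
    reports lesion versus healthy ROI parameters. Includes a seeded synthetic
    phantom generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
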