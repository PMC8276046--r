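Package: rootascent
Title: Automated Root System Architecture Phenotyping from Rhizotron Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for phenotyping root systems of plants
    propagated by cuttings (e.g., grapevine) grown in flat rhizotrons.
    Stitches the two overlapping scan halves of a rhizotron by keypoint
    matching and robust homography estimation, segments roots from the
    background by Otsu thresholding, thins the root mask to a 1-pixel
    skeleton by homotopic thinning, classifies every skeleton pixel
    (endpoint, junction, normal) with a cyclic neighbour change-count rule,
    isolates each adventitious-root skeleton by an ascending traversal from
    the lowest to the highest skeleton point, reconstructs the adventitious
    root free of lateral roots and nodules from its left/right radius
    profile, and extracts architectural traits (root length, local diameter
    profile, lateral counts and lengths, projected area). Also quantifies
    root volume from reconstructed neutron-tomography stacks, including
    open-beam normalisation and outlier removal of radiographs. A synthetic
    root-image generator with exact ground truth supports validation of
    every stage without plant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
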