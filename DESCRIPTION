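Package: linkfuse
Title: Multi-Atlas Segmentation Fusion with Linked Deformable Registrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for multi-atlas image segmentation where pre-computed
    deformable registrations are linked (composed) through intermediate
    atlases instead of registering every atlas directly to the target.
    Provides cubic B-spline free-form deformations and dense displacement
    fields with composition and warping, signed Euclidean distance-map
    label fusion with probabilistic similarity-based weights, segmentation
    quality metrics (Dice similarity coefficient, fractional mean absolute
    surface distance), a leave-one-out evaluation engine that quantifies
    segmentation-quality decay as a function of the number of composed
    registrations, and a synthetic phantom population generator for
    controlled registration-error experiments.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
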