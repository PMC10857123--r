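Package: torsobaro
Title: Torsobarography: Posture Analysis from Dorsal Torso Pressure Images
Version: 0.1.0
Authors@R:
    person("Torsobaro", "Maintainers", email = "maintainers@torsobaro.invalid",
           role = c("aut", "cre"))
Description: Analysis pipeline for torsobarography, a topographic posture
    analysis method based on the dorsal pressure distribution of the torso
    measured in a lying position with a capacitive pressure-sensor mat.
    Provides readers and writers for plain-text pressure recordings,
    medial-frame selection, filtering, mirror-symmetry alignment
    (derotation and centring), region-of-interest mask fitting, anatomical
    landmark detection from the central intensity profile, extraction of
    the full set of posture parameters (frontal and sagittal spine shape,
    shoulder contour, scapulae, torso symmetry, waist contour, pelvic
    posture), intra-observer reliability statistics (ICC(1,1) with exact
    F-based confidence intervals, mean CV, mean SD, classification bands),
    and a parametric phantom generator for synthetic torso imprints and
    repeated-measurement studies with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
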