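Package: glenosim
Title: Patient-Specific Glenohumeral Joint Biomechanics at Desk Scale
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric synthetic scapular anatomy, geometric fitting of the
    glenohumeral joint (sphere, plane and circle fits, critical shoulder angle
    and glenoid inclination morphometrics, stature scaling), template-to-target
    surface registration with accuracy metrics, a reduced-order inverse-dynamics
    shoulder model with cubic-cost muscle recruitment under a glenoid
    stability-cone constraint, concavity-compression instability ratios and
    passive-stability polygons, and one-dimensional statistical parametric
    mapping for cohort comparison of force curves between rotator-cuff-tear-like
    and osteoarthritis-like scapular morphologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
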