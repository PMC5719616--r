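Package: stancelimb
Title: Muscle-Force-Loaded Finite Element Analysis of the Lower Limb During Stance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for loading a finite-element model of the
    lower limb with muscle forces during the stance phase of gait. Provides a
    synthetic-anatomy generator (tube/frustum bone meshes with attachment
    patches, landmarks and gait-position tables), static muscle-force
    estimation on a three-segment linkage using the min/max recruitment
    criterion, mapping of recruited forces to bone attachment areas as
    distributed tractions with action-reaction pairing, a linear-elastic
    four-node tetrahedral finite-element solver with grounded high-stiffness
    springs, weak stabilisation springs, tendon springs and remote-point
    couplings, and a three-criterion validation procedure comparing the
    femoral-head reaction of the finite-element model against the rigid-body
    hip reaction at five stance positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    boot,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
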