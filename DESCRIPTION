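Package: helixcv
Title: Collective Helix Motions in Four-Helix Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body collective variables (piston shift, axial rotation,
    tilt angle) for parallel four-helix bundles such as the HAMP signal-relay
    domain, with analytic gradients and a finite-difference validator;
    bundle-quality analyses (helical RMSD, backbone i to i+4 hydrogen bonds,
    Crick-angle deviation from ideal knobs-into-holes packing, piston-state
    classification, negative-log-probability surfaces); a well-tempered
    metadynamics engine with wall potentials, free-energy recovery from
    deposited hills, and time-dependent bias-offset reweighting, runnable on
    toy Langevin systems; and a synthetic helix-bundle generator with
    injectable piston, rotation and tilt motions for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
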