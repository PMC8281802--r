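Package: ringenm
Title: Elastic Network Models of Stacked Protein Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained (one bead per C-alpha) consensus elastic
    network models of Cn-symmetric stacked protein rings such as Vipp1/IM30,
    PspA and ESCRT-III polymers. Decomposes a ring coordinate model into
    rungs and azimuthal slots, derives a consensus spring network for an
    average rung together with an inter-rung contact map, relaxes cylindrical
    stacks of 2-10 rungs to their elastic equilibrium, and quantifies the
    emergent dome-shaped curvature through helix tilt angles, per-interface
    rotations, diameter profiles and superposition RMSDs. Includes a
    synthetic ring generator with exact geometric ground truth for testing
    every stage without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
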