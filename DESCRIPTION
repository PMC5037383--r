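Package: progpot
Title: Programmable Pairwise Potentials from Coarse-Level Logic Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compiles coarse-level Boolean interaction rules (proximity
    predicates combined with AND/OR/NOT) into smooth [0,1]-valued encoding
    functions that switch pairwise potentials on and off, assembles the
    resulting approximate N-body potential, and simulates its dynamics with
    velocity-Verlet and Langevin (BAOAB) integrators.  Ships fixture builders
    for an inhibitor-molecule mechanism, a bond-breaking chemical reaction
    with transition-state repulsion, and a rule-programmed DNA-transcription
    model, together with trajectory analysis (bond occupancy, event
    sequencing, quasi-static dissociation-work probes, energy-surface scans)
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
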