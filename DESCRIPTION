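Package: mcdem
Title: Multi-Contact Discrete Element Simulation of Powder Compaction
Version: 0.1.0
Authors@R:
    person("mcdem", "developers", email = "mcdem@example.org", role = c("aut", "cre"))
Description: Discrete element method (DEM) toolkit for high-load particle
    compaction. Implements Hertz-Mindlin contacts with Coulomb sliding and
    constant-directional-torque rolling friction, a multi-contact adhesive
    elastic-plastic normal force law with a non-local stress term, deformable
    bonded multi-sphere (BMS) bodies, rigid conventional multi-sphere (CMS)
    clusters with Monte-Carlo mass properties, non-spherical particle shape
    generation and sphere filling of triangulated meshes, particle size
    distribution fitting and sampling, and compaction protocols (single-sphere
    compression, gravity filling, uniaxial die compaction) with a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
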