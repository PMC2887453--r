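Package: enmrelax
Title: Nonlinear Conformational Relaxation in Elastic Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained elastic network models (one bead per C-alpha,
    uniform Hookean springs below a distance cutoff) together with the
    overdamped gradient-flow relaxation dynamics they induce. Provides
    construction of networks from PDB structures or synthetic fixtures,
    numerical integration of the nonlinear relaxation equations with random
    force-prepared and RMS-perturbed initial conditions, normal-mode
    (linearized) analysis at the reference state, reduction of trajectory
    bundles to label-distance traces, the collective mechanical coordinate and
    elastic energy profiles along relaxation paths, harmonic-well fits, and
    bundle dispersion/branching diagnostics for detecting attractive
    relaxation pathways in motor proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
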