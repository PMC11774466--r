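Package: graphvelo
Title: Manifold-Constrained Refinement and Cross-Representation Transfer of
    Single-Cell Velocity Vectors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Refines noisy single-cell RNA velocity vectors by projecting them
    onto the tangent space of the cell-state manifold, approximated locally by
    a k-nearest-neighbor graph in the spirit of local linear embedding. The
    fitted per-cell neighbor coefficients are transferable, enabling velocity
    transformation between representations (gene space, principal components,
    chromatin accessibility, joint embeddings) and extension from a trusted
    gene subset to the whole feature space. Includes manifold-consistency
    (MacK) scoring of per-gene velocities against a cell ordering,
    cell-specific kinetic-rate estimation, ground-truth simulators (stochastic
    toggle-switch bifurcation lifted to a sphere, splicing kinetics with
    transcription bursts and microRNA-driven degradation, small gene
    regulatory network trajectories), evaluation metrics including
    cross-boundary correctness, velocity-trend smoothing and clustering,
    dynamic-time-warping decoupling analysis, and a kernel ridge (RKHS)
    continuous vector-field learner with analytic Jacobians and dose-response
    integration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    mgcv,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
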