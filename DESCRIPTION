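Package: rbeflow
Title: Reduced-Basis Element Method for Unsteady Flow in Modular Vessel Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finite-element and reduced-order modelling of unsteady incompressible
    Navier-Stokes flow in vessel-like geometries assembled from deformed reference
    building blocks (straight tubes and a symmetric bifurcation). Provides Taylor-Hood
    P2-P1 assembly on simplicial meshes, nonconforming coupling of subdomains through
    spectral Lagrange multipliers built from ridge (Chebyshev second kind) polynomials,
    BDF/Newton time integration with a Schur-complement block preconditioner (exact,
    inner-Krylov or SIMPLE local solves), and a POD-Galerkin reduced-order model with
    norm-weighted proper orthogonal decomposition, Piola transformation of velocity
    modes between reference and deformed blocks, supremizer enrichment for pressure
    and coupling stability, and a precomputed (optionally truncated) reduced
    convective tensor. Includes broken-norm error metrics and wall shear stress
    postprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
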