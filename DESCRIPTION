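Package: anisovor
Title: Orientation-Controlled Voronoi Scaffolds for Bone Tissue Engineering
Version: 0.1.0
Authors@R:
    person("LaBS", "Tools", email = "labs-tools@example.org", role = c("aut", "cre"))
Description: Generates stochastic trabecular-like lattice scaffolds from a
    bounded Voronoi tessellation with explicit control of the preferential
    trabecular orientation, and characterizes them fully in silico:
    voxelization and volume-constrained surface smoothing to a target
    porosity, bone-morphometric indices (trabecular thickness and spacing,
    mean-intercept-length fabric and degree of anisotropy, Gaussian surface
    curvature), voxel finite-element homogenization of the effective
    elastic stiffness tensor with directional modulus and anisotropy
    indices, Darcy/Laplace homogenization of the macroscopic permeability
    tensor, and surface octahedral shear strain under compressive loads.
    Includes analytic phantom generators, TIFF/STL/JSON input-output and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Matrix,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
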