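#' Analytic test phantoms
#'
#' Deterministic volumes, graphs and tensors whose ground truth is known in
#' closed form; every oracle in the test-suite (and the CLI demos) is built
#' from these.
#'
#' Kinds:
#' \describe{
#'   \item{`solid_cube` / `empty_cube`}{uniform grids; porosity 0 / 1.}
#'   \item{`ball`}{solid sphere of radius `r` voxels; known volume, area,
#'     curvature `1/r^2` and local thickness `2r`.}
#'   \item{`slab_stack`}{plates normal to z (`plate` solid / `gap` pore
#'     voxels, repeating); strongly transversely isotropic fabric.}
#'   \item{`vertical_rod`}{square solid rod along z filling area fraction
#'     `f` of the cross-section; `Ez = f` exactly at `nu = 0`.}
#'   \item{`axis_channel`}{square pore channel along z through solid,
#'     cross-section fraction `c`; `K_zz / kappa0 = c`, other axes sealed.}
#'   \item{`toy_graph`}{a tripod of three coplanar edges at mutual 120
#'     degrees plus a vertical edge, for graph-statistics oracles.}
#'   \item{`isotropic_C`}{isotropic Voigt stiffness for `(E, nu)`.}
#'   \item{`transverse_C`}{hand-built transversely isotropic stiffness.}
#' }
#'
#' @param kind phantom kind, see Details
#' @param grid grid size per axis (volumes)
#' @param r ball radius, voxels
#' @param plate,gap slab stack thicknesses, voxels
#' @param f rod cross-section area fraction
#' @param c_frac channel cross-section area fraction
#' @param E,nu elastic constants for tensor phantoms
#' @param pitch voxel pitch recorded on volume phantoms (um)
#' @return a list of class `phantom` with the object and its ground truth
#' @export
make_phantom <- function(kind, grid = 32, r = 8, plate = 5, gap = 5,
                         f = 0.25, c_frac = 0.25, E = 1, nu = 0.3,
                         pitch = 1) {
  g <- as.integer(grid)
  vol3 <- function(occ) binary_volume(occ, pitch = pitch)
  obj <- truth <- NULL
  if (kind == "solid_cube") {
    obj <- vol3(array(1L, c(g, g, g)))
    truth <- list(phi = 0)
  } else if (kind == "empty_cube") {
    obj <- vol3(array(0L, c(g, g, g)))
    truth <- list(phi = 1)
  } else if (kind == "ball") {
    ax <- seq_len(g) - 0.5 - g / 2
    dd <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    obj <- vol3(array(as.integer(dd <= r^2), c(g, g, g)))
    truth <- list(phi = 1 - (4 / 3) * pi * r^3 / g^3,
                  area = 4 * pi * r^2, volume = (4 / 3) * pi * r^3,
                  thickness = 2 * r, K_gauss = 1 / r^2)
  } else if (kind == "slab_stack") {
    # gap first, so plates sit in the array interior (a plate touching the
    # array edge has no background below it and reads as thicker)
    period <- plate + gap
    kz <- ((seq_len(g) - 1L) %% period) >= gap
    occ <- array(0L, c(g, g, g))
    occ[, , kz] <- 1L
    obj <- vol3(occ)
    truth <- list(phi = 1 - sum(kz) / g, normal_axis = 3,
                  thickness = plate)
  } else if (kind == "vertical_rod") {
    side <- max(1L, round(sqrt(f) * g))
    occ <- array(0L, c(g, g, g))
    i0 <- floor((g - side) / 2) + 1L
    occ[i0:(i0 + side - 1L), i0:(i0 + side - 1L), ] <- 1L
    obj <- vol3(occ)
    truth <- list(f = side^2 / g^2, Ez_nu0 = side^2 / g^2)
  } else if (kind == "axis_channel") {
    side <- max(1L, round(sqrt(c_frac) * g))
    occ <- array(1L, c(g, g, g))
    i0 <- floor((g - side) / 2) + 1L
    occ[i0:(i0 + side - 1L), i0:(i0 + side - 1L), ] <- 0L
    obj <- vol3(occ)
    truth <- list(c = side^2 / g^2, K_zz = side^2 / g^2,
                  A_kappa = 1)
  } else if (kind == "toy_graph") {
    # tripod: three coplanar unit edges at mutual 120 deg, plus one vertical
    nodes <- rbind(c(0, 0, 0),
                   c(1, 0, 0),
                   c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
                   c(cos(4 * pi / 3), sin(4 * pi / 3), 0),
                   c(0, 0, 1))
    nodes <- sweep(nodes, 2, c(2, 2, 2), "+")
    edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))
    obj <- new_edge_graph(nodes, edges, L = 4)
    truth <- list(planar_angle = 120, degree_center = 4)
  } else if (kind == "isotropic_C") {
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    C <- matrix(0, 6, 6)
    C[1:3, 1:3] <- lam
    diag(C)[1:3] <- lam + 2 * mu
    diag(C)[4:6] <- mu
    obj <- C
    truth <- list(E = E, nu = nu, AZ = 0, AT = 1)
  } else if (kind == "transverse_C") {
    # hexagonal symmetry about z, stiffer along z
    C <- matrix(0, 6, 6)
    C[1, 1] <- C[2, 2] <- 2.0; C[3, 3] <- 4.0
    C[1, 2] <- C[2, 1] <- 0.8
    C[1, 3] <- C[3, 1] <- C[2, 3] <- C[3, 2] <- 0.6
    C[4, 4] <- C[5, 5] <- 0.9
    C[6, 6] <- (C[1, 1] - C[1, 2]) / 2
    obj <- C
    truth <- list(axis = 3)
  } else {
    stop("invalid phantom kind: ", kind)
  }
  structure(list(kind = kind, object = obj, truth = truth),
            class = "phantom")
}
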