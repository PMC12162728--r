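# Voigt order used throughout: (11, 22, 33, 23, 13, 12), engineering shear.

# remove solid components that do not reach the domain boundary (they carry
# no load under affine boundary conditions and make the system singular)
drop_floating_islands <- function(occ) {
  d <- dim(occ)
  lab <- .label_components_cpp(as.integer(occ), d[1], d[2], d[3])
  lab <- array(lab, d)
  touching <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                       lab[, , 1], lab[, , d[3]]))
  touching <- setdiff(touching, 0L)
  if (length(touching) == 0) stop("no load-bearing solid component")
  array(as.integer(lab %in% touching), d)
}

# affine displacement field for a Voigt unit macroscopic strain
affine_displacement <- function(coords, case) {
  eps <- matrix(0, 3, 3)
  if (case <= 3) {
    eps[case, case] <- 1
  } else {
    ij <- list(c(2, 3), c(1, 3), c(1, 2))[[case - 3]]
    eps[ij[1], ij[2]] <- eps[ij[2], ij[1]] <- 0.5  # engineering shear = 1
  }
  coords %*% t(eps)
}

# Solve the voxel-FE system for one or more Dirichlet cases.
# `values`: ndof x ncase matrix of prescribed dof values (used at the fixed
# dofs, and as the CG initial guess everywhere).  `isfix`: logical ndof.
# solver "direct" factorizes the free-dof block once (CHOLMOD, supernodal)
# and back-substitutes all cases; "cg" runs Jacobi-PCG per case; "auto"
# picks direct below a size threshold where the factor fits comfortably in
# memory, CG otherwise.
fem_solve_cases <- function(occ, nu, isfix, values, solver = "auto",
                            tol = 1e-8, maxit = 10000) {
  d <- dim(occ)
  ndof <- length(isfix)
  nfree <- sum(!isfix)
  if (solver == "auto")
    solver <- if (nfree <= 3e5) "direct" else "cg"
  ncase <- ncol(values)
  u <- values
  if (solver == "direct") {
    edofs <- .fem_edofs_cpp(as.integer(occ), d[1], d[2], d[3])
    free_map <- rep(-1L, ndof)
    free_map[!isfix] <- seq_len(nfree) - 1L
    ub <- values
    ub[!isfix, ] <- 0
    Ke <- .hex_ke_cpp(nu)
    asm <- .fem_assemble_cpp(edofs, Ke, free_map, ub, nfree)
    K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                              dims = c(nfree, nfree), symmetric = TRUE)
    ch <- Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
    uf <- as.matrix(Matrix::solve(ch, asm$rhs))
    u[!isfix, ] <- uf
    attr(u, "solver") <- "direct"
    attr(u, "iterations") <- rep(NA_integer_, ncase)
    attr(u, "relres") <- rep(0, ncase)
  } else {
    iters <- integer(ncase)
    relres <- numeric(ncase)
    fixed0 <- which(isfix) - 1L
    for (case in seq_len(ncase)) {
      sol <- .fem_solve_cpp(as.integer(occ), d[1], d[2], d[3], nu,
                            as.integer(fixed0), values[isfix, case],
                            values[, case], tol, as.integer(maxit))
      u[, case] <- sol$u
      iters[case] <- sol$iterations
      relres[case] <- sol$relres
    }
    attr(u, "solver") <- "cg"
    attr(u, "iterations") <- iters
    attr(u, "relres") <- relres
  }
  u
}

#' Effective stiffness tensor by voxel FE homogenization
#'
#' Assembles trilinear 8-node hexahedral elements on the solid voxels
#' (intrinsic modulus `E0 = 1`, Poisson ratio `nu`) and solves the six
#' kinematic-uniform boundary-condition (KUBC) load cases: affine
#' displacements of a unit macroscopic strain are imposed on every node of
#' the RVE boundary.  Each column of the effective stiffness is the
#' volume-averaged stress.  KUBC gives a deterministic upper-bound
#' estimate of the effective stiffness.
#'
#' @param vol a `binary_volume`
#' @param nu Poisson ratio of the constituent material
#' @param solver `"auto"`, `"direct"` (sparse Cholesky, one factorization
#'   for all six cases) or `"cg"` (matrix-free Jacobi-PCG, tolerance 1e-8)
#' @param tol relative CG tolerance
#' @param maxit CG iteration cap
#' @return object of class `stiffness_result`: `C`, `D = solve(C)` (6x6,
#'   Voigt, normalized by `E0`), `Ez` (normalized vertical modulus
#'   `1 / D_3333`), `nu`, per-case solver diagnostics
#' @export
homogenize_stiffness <- function(vol, nu = 0.3, solver = "auto",
                                 tol = 1e-8, maxit = 10000) {
  occ <- drop_floating_islands(vol$occ)
  d <- dim(occ)
  lab <- array(.label_components_cpp(as.integer(occ), d[1], d[2], d[3]), d)
  for (ax in 1:3) {
    lo <- switch(ax, lab[1, , ], lab[, 1, ], lab[, , 1])
    hi <- switch(ax, lab[d[1], , ], lab[, d[2], ], lab[, , d[3]])
    if (!length(intersect(setdiff(unique(lo), 0L), setdiff(unique(hi), 0L))))
      warning(sprintf("solid phase not connected across axis %d", ax))
  }
  nodes <- .fem_nodes_cpp(as.integer(occ), d[1], d[2], d[3])
  coords <- nodes  # grid units, voxel edge = 1
  on_boundary <- nodes[, 1] == 0 | nodes[, 1] == d[1] |
    nodes[, 2] == 0 | nodes[, 2] == d[2] |
    nodes[, 3] == 0 | nodes[, 3] == d[3]
  ndof <- 3 * nrow(nodes)
  isfix <- rep(FALSE, ndof)
  isfix[rep(3 * (which(on_boundary) - 1), each = 3) + 1:3] <- TRUE
  values <- matrix(0, ndof, 6)
  for (case in 1:6)
    values[, case] <- as.numeric(t(affine_displacement(coords, case)))
  u <- fem_solve_cases(occ, nu, isfix, values, solver = solver,
                       tol = tol, maxit = maxit)
  C <- matrix(0, 6, 6)
  for (case in 1:6)
    C[, case] <- .fem_avg_stress_cpp(as.integer(occ), d[1], d[2], d[3], nu,
                                     u[, case])
  iters <- attr(u, "iterations")
  relres <- attr(u, "relres")
  C <- (C + t(C)) / 2
  D <- solve(C)
  structure(list(C = C, D = D, Ez = directional_modulus(D, c(0, 0, 1)),
                 nu = nu, iterations = iters, relres = relres,
                 dim = d, solid_fraction = mean(occ)),
            class = "stiffness_result")
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("<stiffness_result> grid %s, solid fraction %.3f, Ez = %.4g\n",
              paste(x$dim, collapse = "x"), x$solid_fraction, x$Ez))
  invisible(x)
}

#' Directional normalized Young's modulus
#'
#' `E(n) = 1 / (n_i n_j n_k n_l D_ijkl)` where `D_ijkl` is the compliance
#' tensor reconstructed from its Voigt matrix (engineering-shear factors
#' 1/2 per shear index pair).  Even in `n`, so antipodal directions give
#' the same modulus.
#'
#' @param D 6x6 Voigt compliance matrix (or a `stiffness_result`)
#' @param n direction vector (normalized internally), or a matrix of rows
#' @return modulus value(s)
#' @export
directional_modulus <- function(D, n) {
  if (inherits(D, "stiffness_result")) D <- D$D
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  n <- n / sqrt(rowSums(n^2))
  vi <- matrix(c(1, 6, 5, 6, 2, 4, 5, 4, 3), 3, 3)  # tensor index -> Voigt
  f <- c(1, 1, 1, 2, 2, 2)
  out <- numeric(nrow(n))
  for (q in seq_len(nrow(n))) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      p <- vi[i, j]; r <- vi[k, l]
      s <- s + n[q, i] * n[q, j] * n[q, k] * n[q, l] * D[p, r] / (f[p] * f[r])
    }
    out[q] <- 1 / s
  }
  out
}

#' Directional mechanical anisotropy index
#'
#' `A^Z = 1 - E_min / E_max` over the directional modulus sampled on a
#' quasi-uniform hemisphere (at least 500 directions).
#'
#' @param stiff a `stiffness_result` (or Voigt compliance matrix)
#' @param n_dirs number of sampled directions
#' @return list with `AZ`, `E_min`, `E_max`, `E` (sampled field), `dirs`
#' @export
anisotropy_az <- function(stiff, n_dirs = 500) {
  D <- if (inherits(stiff, "stiffness_result")) stiff$D else stiff
  dirs <- fibonacci_directions(n_dirs)
  E <- directional_modulus(D, dirs)
  list(AZ = 1 - min(E) / max(E), E_min = min(E), E_max = max(E),
       E = E, dirs = dirs)
}

#' Tensorial anisotropy index
#'
#' `A^T = 2 (C44 + C55 + C66) / ((C11 + C22 + C33) - (C12 + C13 + C23))
#'  + sum_i alpha(C_Gi)` where `alpha` is the coefficient of variation
#' (sd/mean) over the three Voigt stiffness groups
#' `G1 = {C11, C22, C33}`, `G2 = {C12, C13, C23}`, `G3 = {C44, C55, C66}`.
#' Equals 1 for an isotropic stiffness tensor.
#'
#' @param C 6x6 Voigt stiffness matrix (or a `stiffness_result`)
#' @return scalar index
#' @export
anisotropy_at <- function(C) {
  if (inherits(C, "stiffness_result")) C <- C$C
  g1 <- c(C[1, 1], C[2, 2], C[3, 3])
  g2 <- c(C[1, 2], C[1, 3], C[2, 3])
  g3 <- c(C[4, 4], C[5, 5], C[6, 6])
  den <- sum(g1) - sum(g2)
  if (abs(den) < 1e-12 * max(abs(C)))
    stop("near-zero denominator in the tensorial anisotropy index")
  cv <- function(x) if (mean(x) == 0) 0 else sd(x) / mean(x)
  2 * sum(g3) / den + cv(g1) + cv(g2) + cv(g3)
}

#' Orientation gain of the vertical modulus
#'
#' `<E_z> = Ez(oriented) / Ez(isotropic)`.
#'
#' @param ez_oriented vertical normalized modulus of the oriented scaffold
#' @param ez_iso vertical normalized modulus of the isotropic reference
#' @return the ratio
#' @export
normalized_ez <- function(ez_oriented, ez_iso) {
  if (ez_iso <= 0) stop("isotropic reference modulus must be positive")
  if (ez_oriented <= 0) stop("oriented modulus must be positive")
  ez_oriented / ez_iso
}

#' Octahedral shear strain from principal strains
#'
#' `gamma_oct = (2/3) sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`; zero for a
#' pure hydrostatic strain state.
#'
#' @param e1,e2,e3 principal strains (vectors allowed)
#' @return octahedral shear strain(s)
#' @export
octahedral_shear <- function(e1, e2, e3) {
  (2 / 3) * sqrt((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)
}

#' Surface octahedral shear strain under macroscopic compression
#'
#' Solves a compression of the scaffold along z (default 1% macroscopic
#' strain) and evaluates the octahedral shear strain on the surface voxels
#' (solid voxels with at least one pore face-neighbour inside the grid).
#' Load cases: `"uniaxial"` prescribes the vertical displacement on the two
#' z faces and leaves lateral motion free (two nodes pinned laterally to
#' remove rigid-body modes); `"strip"` additionally blocks the normal
#' displacement on the two x faces (plane-strain-like confinement along x).
#'
#' @param vol a `binary_volume`
#' @param load `"uniaxial"` or `"strip"`
#' @param macro_strain compressive macroscopic strain (positive number)
#' @param nu Poisson ratio
#' @param tol,maxit CG controls
#' @return list of class `strain_field`: `gamma_oct` (surface voxels),
#'   `summary` (quartiles), `principal` (all elements), `voxel` indices,
#'   `surface` logical
#' @export
octahedral_strain <- function(vol, load = c("uniaxial", "strip"),
                              macro_strain = 0.01, nu = 0.3,
                              solver = "auto", tol = 1e-8, maxit = 10000) {
  load <- match.arg(load)
  occ <- drop_floating_islands(vol$occ)
  d <- dim(occ)
  nodes <- .fem_nodes_cpp(as.integer(occ), d[1], d[2], d[3])
  nz <- d[3]
  bot <- which(nodes[, 3] == 0)
  top <- which(nodes[, 3] == nz)
  if (!length(bot) || !length(top))
    stop("solid phase does not reach both z faces")
  fixed <- c(3 * (bot - 1) + 2, 3 * (top - 1) + 2)
  fval <- c(rep(0, length(bot)), rep(-macro_strain * nz, length(top)))
  if (load == "strip") {
    xf <- which(nodes[, 1] == 0 | nodes[, 1] == d[1])
    fixed <- c(fixed, 3 * (xf - 1))
    fval <- c(fval, rep(0, length(xf)))
  } else {
    # pin lateral rigid-body modes at two bottom nodes
    p1 <- bot[which.min(nodes[bot, 1]^2 + nodes[bot, 2]^2)]
    p2 <- bot[which.max(nodes[bot, 1])]
    fixed <- c(fixed, 3 * (p1 - 1), 3 * (p1 - 1) + 1, 3 * (p2 - 1) + 1)
    fval <- c(fval, 0, 0, 0)
  }
  ndof <- 3 * nrow(nodes)
  values <- matrix(as.numeric(t(cbind(0 * nodes[, 1], 0 * nodes[, 2],
                                      -macro_strain * nodes[, 3]))),
                   ndof, 1)
  isfix <- rep(FALSE, ndof)
  isfix[fixed + 1L] <- TRUE
  values[fixed + 1L, 1] <- fval
  u <- fem_solve_cases(occ, nu, isfix, values, solver = solver,
                       tol = tol, maxit = maxit)
  st <- .fem_strains_cpp(as.integer(occ), d[1], d[2], d[3], u[, 1])
  pr <- .principal_strains_cpp(st$eps)
  g <- octahedral_shear(pr[, 1], pr[, 2], pr[, 3])
  # surface voxels: solid with a pore 6-neighbour inside the grid
  surf_map <- array(FALSE, d)
  pad <- array(1L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  core <- function(dx, dy, dz)
    pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
  pore_nb <- (core(1, 0, 0) == 0) | (core(-1, 0, 0) == 0) |
    (core(0, 1, 0) == 0) | (core(0, -1, 0) == 0) |
    (core(0, 0, 1) == 0) | (core(0, 0, -1) == 0)
  surf_map <- occ == 1L & pore_nb
  is_surf <- surf_map[st$voxel]
  gs <- g[is_surf]
  structure(list(gamma_oct = gs,
                 summary = quantile(gs, c(0.25, 0.5, 0.75)),
                 principal = pr, voxel = st$voxel, surface = is_surf,
                 load = load, macro_strain = macro_strain,
                 iterations = attr(u, "iterations")[1],
                 relres = attr(u, "relres")[1]),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %s load, median surface gamma_oct = %.4g\n",
              x$load, x$summary[2]))
  invisible(x)
}

#' Mechano-biologic stimulus
#'
#' `S = gamma_oct / a + v / b` in the Huiskes/Prendergast
#' mechanoregulation framework (`a`, `b` positive constants, `v` the fluid
#' velocity through the pore space).
#'
#' @param gamma_oct octahedral shear strain
#' @param v fluid velocity
#' @param a strain constant (> 0)
#' @param b velocity constant (> 0)
#' @return stimulus value(s)
#' @export
mechanical_stimulus <- function(gamma_oct, v = 0, a = 0.0375, b = 3e-6) {
  if (a <= 0 || b <= 0) stop("constants a and b must be positive")
  gamma_oct / a + v / b
}
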