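# Pore-space Darcy homogenization.  The pore filler (collagen gel /
# granulation tissue) is a homogeneous micro-porous medium of intrinsic
# permeability kappa0; all outputs are normalized by kappa0 (kappa0 = 1
# internally).  Sign convention: Darcy q = -K grad p, which guarantees a
# positive-semidefinite macroscopic K.

pore_percolates <- function(occ, axis) {
  d <- dim(occ)
  pore <- 1L - occ
  lab <- array(.label_components_cpp(as.integer(pore), d[1], d[2], d[3]), d)
  lo <- switch(axis, lab[1, , ], lab[, 1, ], lab[, , 1])
  hi <- switch(axis, lab[d[1], , ], lab[, d[2], ], lab[, , d[3]])
  length(intersect(setdiff(unique(lo), 0L), setdiff(unique(hi), 0L))) > 0
}

#' Pore-pressure Laplace solve
#'
#' Seven-point finite-volume Laplace equation on the pore voxels with
#' Dirichlet pressure equal to the voxel-centre coordinate along `axis` on
#' the pore voxels of the domain boundary faces and zero flux across
#' solid-pore faces (impervious scaffold walls).
#'
#' @param vol a `binary_volume` (solid = 1; the pore phase is solved)
#' @param axis `"x"`, `"y"` or `"z"` (or 1:3)
#' @param tol relative CG tolerance
#' @param maxit iteration cap
#' @return list with the pressure array `p` (NA in solid), iteration count
#'   and relative residual
#' @export
solve_pressure <- function(vol, axis = "z", tol = 1e-10, maxit = 20000) {
  ax <- if (is.character(axis)) match(tolower(axis), c("x", "y", "z"))
        else as.integer(axis)
  if (is.na(ax) || ax < 1 || ax > 3) stop("axis must be x, y or z")
  occ <- vol$occ
  d <- dim(occ)
  if (!pore_percolates(occ, ax))
    stop(sprintf("pore phase does not percolate along axis %d", ax))
  res <- .laplace_solve_cpp(as.integer(1L - occ), d[1], d[2], d[3],
                            ax - 1L, tol, as.integer(maxit))
  if (res$relres > tol * 10)
    stop("pressure solver did not converge")
  list(p = array(res$p, d), iterations = res$iterations,
       relres = res$relres, axis = ax)
}

#' Macroscopic permeability tensor
#'
#' Runs the three unit-gradient Laplace problems and volume-averages the
#' microscopic flux; column `j` of `K / kappa0` is the (negated) mean flux
#' under a unit pressure gradient along axis `j`.  Axes whose pore phase
#' does not percolate contribute zero columns (with a warning).  The tensor
#' is symmetrized; the pre-symmetrization asymmetry norm is reported.
#'
#' @param vol a `binary_volume`
#' @param tol,maxit solver controls
#' @return object of class `permeability_result`: `K` (3x3, units of
#'   kappa0), `evals` (ascending), `evecs`, `A_kappa = 1 - k_min / k_max`,
#'   `asymmetry`, per-axis solver info
#' @export
permeability_tensor <- function(vol, tol = 1e-10, maxit = 20000) {
  occ <- vol$occ
  d <- dim(occ)
  K <- matrix(0, 3, 3)
  info <- list()
  any_perc <- FALSE
  for (ax in 1:3) {
    if (!pore_percolates(occ, ax)) {
      warning(sprintf("pore phase does not percolate along axis %d: zero column",
                      ax))
      next
    }
    any_perc <- TRUE
    sol <- solve_pressure(vol, ax, tol = tol, maxit = maxit)
    g <- .perm_avg_gradient_cpp(as.numeric(sol$p), as.integer(1L - occ),
                                d[1], d[2], d[3], ax - 1L)
    K[, ax] <- g$grad
    info[[ax]] <- list(iterations = sol$iterations, relres = sol$relres,
                       layer_flux = g$layer_flux)
  }
  if (!any_perc) stop("pore phase percolates along no axis")
  asym <- norm(K - t(K), "F") / max(norm(K, "F"), .Machine$double.eps)
  Ks <- (K + t(K)) / 2
  eg <- eigen(Ks, symmetric = TRUE)
  evals <- rev(eg$values)
  evecs <- eg$vectors[, 3:1]
  structure(list(K = Ks, K_raw = K, evals = evals, evecs = evecs,
                 A_kappa = if (evals[3] > 0) 1 - max(0, evals[1]) / evals[3]
                           else NA_real_,
                 asymmetry = asym, info = info),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> diag(K)/kappa0 = (%.4g, %.4g, %.4g), A_kappa = %.3f\n",
              x$K[1, 1], x$K[2, 2], x$K[3, 3], x$A_kappa))
  invisible(x)
}

#' Single-axis macroscopic permeability
#'
#' Runs one Laplace case and returns the diagonal permeability along the
#' chosen axis (units of kappa0); a third of the cost of the full tensor
#' when only one direction is needed.
#'
#' @param vol a `binary_volume`
#' @param axis `"x"`, `"y"` or `"z"`
#' @param tol,maxit solver controls
#' @return scalar `K_aa / kappa0`
#' @export
permeability_axis <- function(vol, axis = "z", tol = 1e-10, maxit = 20000) {
  ax <- if (is.character(axis)) match(tolower(axis), c("x", "y", "z"))
        else as.integer(axis)
  sol <- solve_pressure(vol, ax, tol = tol, maxit = maxit)
  d <- dim(vol$occ)
  g <- .perm_avg_gradient_cpp(as.numeric(sol$p), as.integer(1L - vol$occ),
                              d[1], d[2], d[3], ax - 1L)
  g$grad[ax]
}

#' Directional permeability
#'
#' `k_n = kappa0 n' K n`.
#'
#' @param perm a `permeability_result` (or 3x3 matrix, units of kappa0)
#' @param n direction (normalized internally)
#' @param kappa0 intrinsic small-scale permeability
#' @return directional permeability
#' @export
directional_permeability <- function(perm, n, kappa0 = 1) {
  K <- if (inherits(perm, "permeability_result")) perm$K else perm
  n <- n / sqrt(sum(n^2))
  kappa0 * drop(t(n) %*% K %*% n)
}

#' Fit the isotropic permeability scaling law
#'
#' Least-squares line of the dimensionless permeability `K_iso / kappa0`
#' against the morphometric predictor `Tb.Sp^2 phi^(3/2) / l0^2` (the
#' collagen-foam scaling `kappa = A d^2 phi^(3/2)` with `A = kappa0/l0^2`
#' set to 1).
#'
#' @param k_iso vector of isotropic permeabilities (units of kappa0)
#' @param tb_sp vector of trabecular spacings
#' @param phi vector of porosities
#' @param l0 characteristic foam length (scales the abscissa)
#' @return list of class `scaling_fit`: `slope`, `intercept`, `r_squared`,
#'   data frame `data`
#' @export
fit_permeability_scaling <- function(k_iso, tb_sp, phi, l0 = 1) {
  if (length(k_iso) < 3 || length(unique(phi)) < 3)
    stop("need at least 3 isotropic scaffolds at distinct porosities")
  x <- tb_sp^2 * phi^1.5 / l0^2
  if (diff(range(x)) <= 0) stop("degenerate abscissa")
  fit <- lm(k_iso ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 data = data.frame(x = x, k_iso = k_iso, phi = phi,
                                   tb_sp = tb_sp)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> slope %.4g, R^2 = %.3f (n = %d)\n",
              x$slope, x$r_squared, nrow(x$data)))
  invisible(x)
}
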