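#' Local thickness of a phase (Hildebrand-Ruegsegger)
#'
#' The local thickness at a voxel is the diameter of the largest sphere
#' that is fully contained in the phase and contains that voxel, computed
#' by an exact Euclidean distance transform followed by sphere painting
#' (largest spheres first).  Means are voxel-weighted, following the
#' BoneJ/Fiji convention.  Trabecular thickness Tb.Th is the solid-phase
#' value, trabecular spacing Tb.Sp the pore-phase value.
#'
#' @param vol a `binary_volume`
#' @param phase `"solid"` or `"pore"`
#' @return list with `mean`, `sd` (um), `values` (per-voxel thickness, um)
#'   and `map` (3D array, voxels)
#' @export
local_thickness <- function(vol, phase = c("solid", "pore")) {
  phase <- match.arg(phase)
  occ <- vol$occ
  if (phase == "pore") occ <- 1L - occ
  if (sum(occ) == 0) stop("empty phase")
  d <- dim(occ)
  th <- .local_thickness_cpp(as.integer(occ), d[1], d[2], d[3])
  vals <- th[occ == 1L] * vol$pitch
  list(mean = mean(vals), sd = sd(vals), values = vals,
       map = array(th, d), phase = phase)
}

#' Trabecular thickness and spacing report
#'
#' @param vol a `binary_volume`
#' @return list of class `thickness_report` with `tb_th`, `tb_sp`
#'   (mean/sd in um) and the per-voxel value vectors
#' @export
thickness_report <- function(vol) {
  solid <- local_thickness(vol, "solid")
  pore <- local_thickness(vol, "pore")
  structure(list(
    tb_th = c(mean = solid$mean, sd = solid$sd),
    tb_sp = c(mean = pore$mean, sd = pore$sd),
    tb_th_values = solid$values, tb_sp_values = pore$values
  ), class = "thickness_report")
}

#' @export
print.thickness_report <- function(x, ...) {
  cat(sprintf("<thickness_report> Tb.Th %.0f +- %.0f um, Tb.Sp %.0f +- %.0f um\n",
              x$tb_th["mean"], x$tb_th["sd"], x$tb_sp["mean"], x$tb_sp["sd"]))
  invisible(x)
}

#' Mean-intercept-length fabric tensor and degree of anisotropy
#'
#' Parallel test lines are cast through the volume along quasi-uniform
#' directions; for each direction the mean intercept length is the total
#' line length in solid divided by the number of solid intercepts.  The
#' classic fabric quadric `MIL(n)^-2 = n' M n` is fitted by least squares;
#' the eigenvalues of `M` give the degree of anisotropy
#' `DA = 1 - lambda_min / lambda_max` (0 for a geometrically isotropic
#' structure).  The eigenvector of `lambda_max` is the direction of the
#' most frequent intercepts (e.g. the normal of a stack of plates).
#'
#' @param vol a `binary_volume`
#' @param n_directions number of test directions (Fibonacci hemisphere)
#' @param line_spacing spacing of parallel lines, voxels
#' @param step marching step along each line, voxels
#' @return list of class `mil_fabric`: `tensor`, `evals` (ascending),
#'   `evecs`, `DA`, `mil` (per-direction table), `n_skipped`
#' @export
mil_fabric <- function(vol, n_directions = 257, line_spacing = 2,
                       step = 0.5) {
  occ <- vol$occ
  if (sum(occ) == 0 || sum(occ) == length(occ))
    stop("both phases must be present")
  d <- dim(occ)
  dirs <- fibonacci_directions(n_directions)
  jit <- runif(2 * n_directions)
  scan <- .mil_scan_cpp(as.integer(occ), d[1], d[2], d[3], dirs,
                        line_spacing, step, jit)
  ok <- scan$n_runs > 0 & scan$solid_len > 0
  n_skipped <- sum(!ok)
  if (n_skipped > 0.5 * n_directions)
    stop("more than half of the MIL directions had no intercepts")
  if (n_skipped > 0)
    warning(sprintf("%d MIL direction(s) without intercepts skipped",
                    n_skipped))
  mil <- scan$solid_len[ok] / scan$n_runs[ok]
  u <- dirs[ok, , drop = FALSE]
  y <- mil^-2
  X <- cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
             2 * u[, 1] * u[, 2], 2 * u[, 1] * u[, 3], 2 * u[, 2] * u[, 3])
  b <- stats::lsfit(X, y, intercept = FALSE)$coefficients
  M <- matrix(c(b[1], b[4], b[5],
                b[4], b[2], b[6],
                b[5], b[6], b[3]), 3, 3)
  eg <- eigen(M, symmetric = TRUE)  # decreasing order
  evals <- rev(eg$values)
  evecs <- eg$vectors[, 3:1]
  if (evals[1] <= 0)
    warning("MIL fabric tensor is not positive definite; DA unreliable")
  structure(list(tensor = M, evals = evals, evecs = evecs,
                 DA = 1 - evals[1] / evals[3],
                 mil = data.frame(nx = u[, 1], ny = u[, 2], nz = u[, 3],
                                  mil = mil),
                 n_skipped = n_skipped),
            class = "mil_fabric")
}

#' @export
print.mil_fabric <- function(x, ...) {
  cat(sprintf("<mil_fabric> DA = %.3f (eigenvalues %.3g / %.3g / %.3g)\n",
              x$DA, x$evals[1], x$evals[2], x$evals[3]))
  invisible(x)
}

#' Gaussian curvature of a surface mesh
#'
#' Per-vertex Gaussian curvature by the angle-deficit (discrete
#' Gauss-Bonnet) estimator normalized by one-third barycentric vertex area;
#' principal curvatures are recovered from the paired cotangent-Laplacian
#' mean curvature: `k_1,2 = H +- sqrt(H^2 - K)`.
#'
#' @param mesh a watertight `tri_mesh`
#' @return list of class `curvature_field`: `K` (1/um^2), `H`, `k1`, `k2`
#'   (1/um), `vertex_area` (um^2), `deficit` (radians; sums to `2 pi chi`)
#' @export
gaussian_curvature <- function(mesh) {
  if (!mesh_is_watertight(mesh)) stop("mesh is not watertight/manifold")
  res <- .mesh_curvature_cpp(mesh$vertices, mesh$faces)
  disc <- res$H^2 - res$K
  k1 <- k2 <- numeric(length(disc))
  ok <- disc >= 0
  k1[ok] <- res$H[ok] + sqrt(disc[ok])
  k2[ok] <- res$H[ok] - sqrt(disc[ok])
  # where the two discrete estimators disagree (H^2 < K), fall back to the
  # umbilic assumption so that K = k1 * k2 is preserved
  k1[!ok] <- k2[!ok] <- sign(res$H[!ok]) * sqrt(pmax(res$K[!ok], 0))
  structure(list(K = res$K, H = res$H, k1 = k1, k2 = k2,
                 vertex_area = res$area, deficit = res$deficit),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("<curvature_field> %d vertices, mean K = %.4g, %.1f%% area with K <= 0\n",
              length(x$K), mean(x$K),
              100 * sum(x$vertex_area[x$K <= 0]) / sum(x$vertex_area)))
  invisible(x)
}
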