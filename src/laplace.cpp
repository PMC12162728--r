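#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Finite-volume Laplace solver on the pore phase: one unknown per pore
// voxel, unit face conductance between pore neighbours, zero flux across
// pore-solid faces (impervious scaffold walls), Dirichlet p = voxel-centre
// coordinate on pore voxels of the domain boundary faces.  Jacobi-
// preconditioned CG (the preconditioner equals the diagonal = number of
// pore neighbours).

namespace {
inline size_t idx3(int i, int j, int k, int nx, int ny) {
  return (size_t)i + nx * ((size_t)j + (size_t)ny * k);
}
}

// [[Rcpp::export(name = ".laplace_solve_cpp")]]
List laplace_solve_cpp(IntegerVector pore, int nx, int ny, int nz, int axis,
                       double tol, int maxit) {
  const size_t N = (size_t)nx * ny * nz;
  std::vector<int> id(N, -1);
  std::vector<int> cells;
  for (size_t q = 0; q < N; ++q)
    if (pore[q]) {
      id[q] = (int)cells.size();
      cells.push_back((int)q);
    }
  const size_t n = cells.size();
  if (n == 0) stop("no pore voxels");

  std::vector<double> p(n, 0.0), diag(n, 0.0);
  std::vector<char> isfix(n, 0);

  auto coord = [&](int c, int ax) {
    const int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    const int v[3] = {i, j, k};
    return v[ax];
  };
  const int dims[3] = {nx, ny, nz};

  for (size_t q = 0; q < n; ++q) {
    const int c = cells[q];
    const int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 ||
        k == nz - 1) {
      isfix[q] = 1;
      p[q] = coord(c, axis) + 0.5;  // voxel-centre coordinate, pitch 1
    }
  }
  (void)dims;

  // neighbour lists via offsets
  const int offs[6][4] = {{-1, 0, 0, 0}, {1, 0, 0, 0}, {0, -1, 0, 1},
                          {0, 1, 0, 1},  {0, 0, -1, 2}, {0, 0, 1, 2}};
  auto nbr = [&](int c, int t) -> int {
    const int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    const int ii = i + offs[t][0], jj = j + offs[t][1], kk = k + offs[t][2];
    if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
      return -1;
    return (int)idx3(ii, jj, kk, nx, ny);
  };

  for (size_t q = 0; q < n; ++q) {
    const int c = cells[q];
    double d = 0;
    for (int t = 0; t < 6; ++t) {
      const int m = nbr(c, t);
      if (m >= 0 && id[m] >= 0) d += 1.0;
    }
    diag[q] = (d > 0) ? d : 1.0;
  }

  auto matvec = [&](const std::vector<double>& x, std::vector<double>& y) {
    for (size_t q = 0; q < n; ++q) {
      const int c = cells[q];
      double s = 0, d = 0;
      for (int t = 0; t < 6; ++t) {
        const int m = nbr(c, t);
        if (m >= 0 && id[m] >= 0) {
          s += x[id[m]];
          d += 1.0;
        }
      }
      y[q] = d * x[q] - s;  // graph Laplacian row
    }
  };

  std::vector<double> r(n), z(n), pd(n), Ap(n);
  matvec(p, r);
  for (size_t q = 0; q < n; ++q) r[q] = isfix[q] ? 0.0 : -r[q];
  double rz = 0, r0 = 0;
  for (size_t q = 0; q < n; ++q) {
    z[q] = r[q] / diag[q];
    rz += r[q] * z[q];
    r0 += r[q] * r[q];
  }
  r0 = std::sqrt(r0);
  pd = z;
  int it = 0;
  double rn = r0;
  const double target = tol * std::max(r0, 1e-300);
  for (; it < maxit && rn > target; ++it) {
    matvec(pd, Ap);
    for (size_t q = 0; q < n; ++q)
      if (isfix[q]) Ap[q] = 0.0;
    double pAp = 0;
    for (size_t q = 0; q < n; ++q) pAp += pd[q] * Ap[q];
    if (pAp <= 0) break;
    const double alpha = rz / pAp;
    rn = 0;
    for (size_t q = 0; q < n; ++q) {
      p[q] += alpha * pd[q];
      r[q] -= alpha * Ap[q];
      rn += r[q] * r[q];
    }
    rn = std::sqrt(rn);
    double rz_new = 0;
    for (size_t q = 0; q < n; ++q) {
      z[q] = r[q] / diag[q];
      rz_new += r[q] * z[q];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (size_t q = 0; q < n; ++q) pd[q] = z[q] + beta * pd[q];
  }

  NumericVector field(N, NA_REAL);
  for (size_t q = 0; q < n; ++q) field[cells[q]] = p[q];
  field.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["p"] = field, _["iterations"] = it,
                      _["relres"] = (r0 > 0) ? rn / r0 : 0.0);
}

// Volume-averaged pressure gradient of a solved field: component i is the
// sum of (p_hi - p_lo) over all pore-pore faces perpendicular to axis i,
// normalized by the dual volume (n_i - 1) * n_j * n_k, which makes an
// all-pore cube under a unit boundary gradient give exactly 1.
// Also returns the net flux through each cross-sectional layer along
// `axis` for conservation checks.
// [[Rcpp::export(name = ".perm_avg_gradient_cpp")]]
List perm_avg_gradient_cpp(NumericVector pfield, IntegerVector pore, int nx,
                           int ny, int nz, int axis) {
  double g[3] = {0, 0, 0};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t c = idx3(i, j, k, nx, ny);
        if (!pore[c]) continue;
        if (i + 1 < nx && pore[c + 1]) g[0] += pfield[c + 1] - pfield[c];
        if (j + 1 < ny && pore[c + nx]) g[1] += pfield[c + nx] - pfield[c];
        if (k + 1 < nz && pore[c + (size_t)nx * ny])
          g[2] += pfield[c + (size_t)nx * ny] - pfield[c];
      }
  const double nd[3] = {(double)nx, (double)ny, (double)nz};
  NumericVector grad(3);
  for (int a = 0; a < 3; ++a) {
    const double dual = (nd[a] - 1.0) * nd[(a + 1) % 3] * nd[(a + 2) % 3];
    grad[a] = (dual > 0) ? g[a] / dual : 0.0;
  }
  // layer fluxes along `axis`
  const int nlay = (axis == 0 ? nx : (axis == 1 ? ny : nz)) - 1;
  NumericVector layer(nlay > 0 ? nlay : 0);
  for (int l = 0; l < nlay; ++l) {
    double s = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if ((axis == 0 && i != l) || (axis == 1 && j != l) ||
              (axis == 2 && k != l))
            continue;
          const size_t c = idx3(i, j, k, nx, ny);
          if (!pore[c]) continue;
          size_t m = c;
          if (axis == 0) m = c + 1;
          if (axis == 1) m = c + nx;
          if (axis == 2) m = c + (size_t)nx * ny;
          if (pore[m]) s += pfield[m] - pfield[c];
        }
    layer[l] = s;
  }
  return List::create(_["grad"] = grad, _["layer_flux"] = layer);
}
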