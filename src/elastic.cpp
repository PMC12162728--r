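#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Matrix-free voxel finite elements: 8-node trilinear hexahedra on the solid
// voxels, one element per voxel (unit edge; the element stiffness scales
// linearly with voxel size, which cancels in all normalized outputs).
// Voigt order (11, 22, 33, 23, 13, 12) with engineering shear strains.
// Dirichlet constraints are passed as (active-dof id, value) pairs; the
// solver is Jacobi-preconditioned conjugate gradients on the free dofs.

namespace {

// local node a = i + 2j + 4k, natural coords xi_a = 2i-1 etc.
void shape_grad(double xi, double eta, double zeta, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    const double sx = (a & 1) ? 1.0 : -1.0;
    const double sy = (a & 2) ? 1.0 : -1.0;
    const double sz = (a & 4) ? 1.0 : -1.0;
    // d/dx = d/dxi * 2 for a unit voxel
    dN[a][0] = 0.25 * sx * (1 + sy * eta) * (1 + sz * zeta);
    dN[a][1] = 0.25 * sy * (1 + sx * xi) * (1 + sz * zeta);
    dN[a][2] = 0.25 * sz * (1 + sx * xi) * (1 + sy * eta);
  }
}

void bmat(const double dN[8][3], double B[6][24]) {
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 24; ++c) B[r][c] = 0.0;
  for (int a = 0; a < 8; ++a) {
    const int c = 3 * a;
    B[0][c + 0] = dN[a][0];
    B[1][c + 1] = dN[a][1];
    B[2][c + 2] = dN[a][2];
    B[3][c + 1] = dN[a][2]; B[3][c + 2] = dN[a][1];  // gamma_23
    B[4][c + 0] = dN[a][2]; B[4][c + 2] = dN[a][0];  // gamma_13
    B[5][c + 0] = dN[a][1]; B[5][c + 1] = dN[a][0];  // gamma_12
  }
}

void dmat(double nu, double D[6][6]) {
  const double E = 1.0;
  const double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  const double mu = E / (2 * (1 + nu));
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) D[r][c] = 0.0;
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) D[r][c] = lam;
    D[r][r] = lam + 2 * mu;
    D[r + 3][r + 3] = mu;
  }
}

void hex_ke(double nu, double Ke[24][24]) {
  double D[6][6];
  dmat(nu, D);
  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < 24; ++c) Ke[r][c] = 0.0;
  const double g = 1.0 / std::sqrt(3.0);
  const double w = 0.125;  // detJ = (1/2)^3 per gauss point, weight 1
  for (int gx = 0; gx < 2; ++gx)
    for (int gy = 0; gy < 2; ++gy)
      for (int gz = 0; gz < 2; ++gz) {
        double dN[8][3], B[6][24], DB[6][24];
        shape_grad(g * (2 * gx - 1), g * (2 * gy - 1), g * (2 * gz - 1), dN);
        bmat(dN, B);
        for (int r = 0; r < 6; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0;
            for (int t = 0; t < 6; ++t) s += D[r][t] * B[t][c];
            DB[r][c] = s;
          }
        for (int r = 0; r < 24; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0;
            for (int t = 0; t < 6; ++t) s += B[t][r] * DB[t][c];
            Ke[r][c] += w * s;
          }
      }
}

struct FemGrid {
  int nx, ny, nz;
  std::vector<int> elems;       // linear voxel index of each solid element
  std::vector<int> node_map;    // global grid-node id -> active node id (-1)
  std::vector<int> node_gid;    // active node id -> global grid-node id
  std::vector<int> edofs;       // nelem x 24 active dof ids
};

void build_grid(const IntegerVector& occ, int nx, int ny, int nz, FemGrid& G) {
  G.nx = nx; G.ny = ny; G.nz = nz;
  const int NX = nx + 1, NY = ny + 1;
  G.node_map.assign((size_t)NX * NY * (nz + 1), -1);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (occ[i + nx * (j + (size_t)ny * k)]) {
          G.elems.push_back(i + nx * (j + ny * k));
          for (int a = 0; a < 8; ++a) {
            const int ii = i + (a & 1), jj = j + ((a >> 1) & 1),
                      kk = k + ((a >> 2) & 1);
            G.node_map[ii + NX * (jj + (size_t)NY * kk)] = 0;
          }
        }
  for (size_t g = 0; g < G.node_map.size(); ++g)
    if (G.node_map[g] == 0) {
      G.node_map[g] = (int)G.node_gid.size();
      G.node_gid.push_back((int)g);
    }
  G.edofs.resize(G.elems.size() * 24);
  for (size_t e = 0; e < G.elems.size(); ++e) {
    const int c = G.elems[e];
    const int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    for (int a = 0; a < 8; ++a) {
      const int ii = i + (a & 1), jj = j + ((a >> 1) & 1), kk = k + ((a >> 2) & 1);
      const int an = G.node_map[ii + NX * (jj + (size_t)NY * kk)];
      for (int d = 0; d < 3; ++d) G.edofs[24 * e + 3 * a + d] = 3 * an + d;
    }
  }
}

void matvec(const FemGrid& G, const double Ke[24][24],
            const std::vector<double>& u, std::vector<double>& y) {
  std::fill(y.begin(), y.end(), 0.0);
  double ue[24], ye[24];
  for (size_t e = 0; e < G.elems.size(); ++e) {
    const int* ed = &G.edofs[24 * e];
    for (int a = 0; a < 24; ++a) ue[a] = u[ed[a]];
    for (int r = 0; r < 24; ++r) {
      double s = 0;
      const double* kr = Ke[r];
      for (int c = 0; c < 24; ++c) s += kr[c] * ue[c];
      ye[r] = s;
    }
    for (int a = 0; a < 24; ++a) y[ed[a]] += ye[a];
  }
}

}  // namespace

// [[Rcpp::export(name = ".hex_ke_cpp")]]
NumericMatrix hex_ke_cpp(double nu) {
  double Ke[24][24];
  hex_ke(nu, Ke);
  NumericMatrix out(24, 24);
  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < 24; ++c) out(r, c) = Ke[r][c];
  return out;
}

// Active node table: global (i,j,k) grid coordinates of each active node,
// in active-node order (ascending global node id).
// [[Rcpp::export(name = ".fem_nodes_cpp")]]
IntegerMatrix fem_nodes_cpp(IntegerVector occ, int nx, int ny, int nz) {
  FemGrid G;
  build_grid(occ, nx, ny, nz, G);
  IntegerMatrix out((int)G.node_gid.size(), 3);
  const int NX = nx + 1, NY = ny + 1;
  for (size_t q = 0; q < G.node_gid.size(); ++q) {
    const int g = G.node_gid[q];
    out(q, 0) = g % NX;
    out(q, 1) = (g / NX) % NY;
    out(q, 2) = g / (NX * NY);
  }
  return out;
}

// PCG solve of K u = 0 subject to u[fixed] = fixed_val, starting from u0.
// fixed: 0-based active dof ids.  Returns u, iterations, relative residual.
// [[Rcpp::export(name = ".fem_solve_cpp")]]
List fem_solve_cpp(IntegerVector occ, int nx, int ny, int nz, double nu,
                   IntegerVector fixed, NumericVector fixed_val,
                   NumericVector u0, double tol, int maxit) {
  FemGrid G;
  build_grid(occ, nx, ny, nz, G);
  double Ke[24][24];
  hex_ke(nu, Ke);
  const size_t ndof = 3 * G.node_gid.size();
  if ((size_t)u0.size() != ndof) stop("u0 has wrong length");
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<char> isfix(ndof, 0);
  for (int q = 0; q < fixed.size(); ++q) {
    isfix[fixed[q]] = 1;
    u[fixed[q]] = fixed_val[q];
  }
  // Jacobi diagonal
  std::vector<double> diag(ndof, 0.0);
  for (size_t e = 0; e < G.elems.size(); ++e)
    for (int a = 0; a < 24; ++a) diag[G.edofs[24 * e + a]] += Ke[a][a];
  for (size_t q = 0; q < ndof; ++q)
    if (diag[q] <= 0) diag[q] = 1.0;

  std::vector<double> r(ndof), z(ndof), p(ndof), Ap(ndof);
  matvec(G, Ke, u, r);
  for (size_t q = 0; q < ndof; ++q) r[q] = isfix[q] ? 0.0 : -r[q];
  double rz = 0, r0 = 0;
  for (size_t q = 0; q < ndof; ++q) {
    z[q] = r[q] / diag[q];
    rz += r[q] * z[q];
    r0 += r[q] * r[q];
  }
  r0 = std::sqrt(r0);
  p = z;
  int it = 0;
  double rn = r0;
  const double target = tol * std::max(r0, 1e-300);
  for (; it < maxit && rn > target; ++it) {
    matvec(G, Ke, p, Ap);
    for (size_t q = 0; q < ndof; ++q)
      if (isfix[q]) Ap[q] = 0.0;
    double pAp = 0;
    for (size_t q = 0; q < ndof; ++q) pAp += p[q] * Ap[q];
    if (pAp <= 0) break;
    const double alpha = rz / pAp;
    rn = 0;
    for (size_t q = 0; q < ndof; ++q) {
      u[q] += alpha * p[q];
      r[q] -= alpha * Ap[q];
      rn += r[q] * r[q];
    }
    rn = std::sqrt(rn);
    double rz_new = 0;
    for (size_t q = 0; q < ndof; ++q) {
      z[q] = r[q] / diag[q];
      rz_new += r[q] * z[q];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (size_t q = 0; q < ndof; ++q) p[q] = z[q] + beta * p[q];
  }
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["iterations"] = it,
                      _["relres"] = (r0 > 0) ? rn / r0 : 0.0);
}

// Element centroid strains (Voigt, engineering shear), one row per solid
// element in grid scan order; first column block gives the voxel index.
// [[Rcpp::export(name = ".fem_strains_cpp")]]
List fem_strains_cpp(IntegerVector occ, int nx, int ny, int nz,
                     NumericVector u) {
  FemGrid G;
  build_grid(occ, nx, ny, nz, G);
  double dN[8][3], B[6][24];
  shape_grad(0, 0, 0, dN);
  bmat(dN, B);
  const size_t ne = G.elems.size();
  NumericMatrix eps((int)ne, 6);
  IntegerVector vox((int)ne);
  for (size_t e = 0; e < ne; ++e) {
    const int* ed = &G.edofs[24 * e];
    for (int r = 0; r < 6; ++r) {
      double s = 0;
      for (int c = 0; c < 24; ++c) s += B[r][c] * u[ed[c]];
      eps(e, r) = s;
    }
    vox[e] = G.elems[e] + 1;  // 1-based linear voxel index
  }
  return List::create(_["eps"] = eps, _["voxel"] = vox);
}

// Volume-averaged stress (over the full RVE volume nx*ny*nz).
// [[Rcpp::export(name = ".fem_avg_stress_cpp")]]
NumericVector fem_avg_stress_cpp(IntegerVector occ, int nx, int ny, int nz,
                                 double nu, NumericVector u) {
  FemGrid G;
  build_grid(occ, nx, ny, nz, G);
  double D[6][6], dN[8][3], B[6][24];
  dmat(nu, D);
  shape_grad(0, 0, 0, dN);
  bmat(dN, B);
  std::vector<double> sig(6, 0.0);
  for (size_t e = 0; e < G.elems.size(); ++e) {
    const int* ed = &G.edofs[24 * e];
    double epsv[6];
    for (int r = 0; r < 6; ++r) {
      double s = 0;
      for (int c = 0; c < 24; ++c) s += B[r][c] * u[ed[c]];
      epsv[r] = s;
    }
    for (int r = 0; r < 6; ++r) {
      double s = 0;
      for (int t = 0; t < 6; ++t) s += D[r][t] * epsv[t];
      sig[r] += s;
    }
  }
  const double V = (double)nx * ny * nz;
  NumericVector out(6);
  for (int r = 0; r < 6; ++r) out[r] = sig[r] / V;
  return out;
}

// Closed-form eigenvalues of symmetric 3x3 strain tensors given in Voigt
// form with engineering shear; returns principal strains sorted descending.
// [[Rcpp::export(name = ".principal_strains_cpp")]]
NumericMatrix principal_strains_cpp(NumericMatrix eps) {
  const int n = eps.nrow();
  NumericMatrix out(n, 3);
  for (int q = 0; q < n; ++q) {
    const double a11 = eps(q, 0), a22 = eps(q, 1), a33 = eps(q, 2);
    const double a23 = 0.5 * eps(q, 3), a13 = 0.5 * eps(q, 4),
                 a12 = 0.5 * eps(q, 5);
    const double tr = a11 + a22 + a33;
    const double m = tr / 3.0;
    const double b11 = a11 - m, b22 = a22 - m, b33 = a33 - m;
    const double p2 = b11 * b11 + b22 * b22 + b33 * b33 +
                      2 * (a12 * a12 + a13 * a13 + a23 * a23);
    if (p2 < 1e-30) {
      out(q, 0) = out(q, 1) = out(q, 2) = m;
      continue;
    }
    const double p = std::sqrt(p2 / 6.0);
    // det(B/p)/2
    const double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
    const double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
    double r = 0.5 * (c11 * (c22 * c33 - c23 * c23) -
                      c12 * (c12 * c33 - c23 * c13) +
                      c13 * (c12 * c23 - c22 * c13));
    r = std::min(1.0, std::max(-1.0, r));
    const double phi = std::acos(r) / 3.0;
    const double e1 = m + 2 * p * std::cos(phi);
    const double e3 = m + 2 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    const double e2 = tr - e1 - e3;
    out(q, 0) = e1;
    out(q, 1) = e2;
    out(q, 2) = e3;
  }
  return out;
}
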