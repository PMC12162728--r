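#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Voxel-volume kernels: capsule rasterization of the edge skeleton, separable
// Gaussian smoothing, exact-count thresholding (the volume constraint of the
// smoothing loop), squared Euclidean distance transform, Hildebrand-
// Ruegsegger local thickness, 6-connected component labelling and the
// mean-intercept-length direction scan.  Arrays are column-major (i fastest),
// matching R's array layout; voxel centres sit at (i + 0.5) * pitch.

namespace {
inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}
}

// [[Rcpp::export(name = ".rasterize_edges_cpp")]]
IntegerVector rasterize_edges_cpp(NumericMatrix nodes, IntegerMatrix edges,
                                  int nx, int ny, int nz, double pitch,
                                  double thickness) {
  IntegerVector occ(nx * ny * nz, 0);
  const double r = thickness / 2.0, r2 = r * r;
  for (int e = 0; e < edges.nrow(); ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    const double ax = nodes(a, 0), ay = nodes(a, 1), az = nodes(a, 2);
    const double bx = nodes(b, 0), by = nodes(b, 1), bz = nodes(b, 2);
    const double dx = bx - ax, dy = by - ay, dz = bz - az;
    const double len2 = dx * dx + dy * dy + dz * dz;
    const double pad = r + pitch;
    int i0 = std::max(0, (int)std::floor((std::min(ax, bx) - pad) / pitch));
    int i1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + pad) / pitch));
    int j0 = std::max(0, (int)std::floor((std::min(ay, by) - pad) / pitch));
    int j1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + pad) / pitch));
    int k0 = std::max(0, (int)std::floor((std::min(az, bz) - pad) / pitch));
    int k1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + pad) / pitch));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          const double px = (i + 0.5) * pitch, py = (j + 0.5) * pitch,
                       pz = (k + 0.5) * pitch;
          double t = 0.0;
          if (len2 > 0.0)
            t = ((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2;
          t = std::min(1.0, std::max(0.0, t));
          const double qx = ax + t * dx - px, qy = ay + t * dy - py,
                       qz = az + t * dz - pz;
          if (qx * qx + qy * qy + qz * qz <= r2)
            occ[idx3(i, j, k, nx, ny)] = 1;
        }
  }
  occ.attr("dim") = IntegerVector::create(nx, ny, nz);
  return occ;
}

// Separable Gaussian blur with reflecting boundaries.
// [[Rcpp::export(name = ".gaussian_blur3_cpp")]]
NumericVector gaussian_blur3_cpp(NumericVector vol, int nx, int ny, int nz,
                                 double sigma) {
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (auto& w : ker) w /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * a[idx3(reflect(i + t, nx), j, k, nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * b[idx3(i, reflect(j + t, ny), k, nx, ny)];
        a[idx3(i, j, k, nx, ny)] = acc;
      }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * a[idx3(i, j, reflect(k + t, nz), nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Binarize `vol` keeping exactly n_solid voxels: the n_solid largest values,
// ties resolved in ascending linear-index order (deterministic).
// [[Rcpp::export(name = ".threshold_to_count_cpp")]]
IntegerVector threshold_to_count_cpp(NumericVector vol, int n_solid) {
  const int n = vol.size();
  if (n_solid < 0 || n_solid > n) stop("n_solid out of range");
  IntegerVector occ(n, 0);
  if (n_solid == 0) { occ.attr("dim") = vol.attr("dim"); return occ; }
  std::vector<double> v(vol.begin(), vol.end());
  std::nth_element(v.begin(), v.begin() + (n_solid - 1), v.end(),
                   std::greater<double>());
  const double thr = v[n_solid - 1];
  int taken = 0;
  for (int i = 0; i < n; ++i)
    if (vol[i] > thr) { occ[i] = 1; ++taken; }
  for (int i = 0; i < n && taken < n_solid; ++i)
    if (vol[i] == thr && occ[i] == 0) { occ[i] = 1; ++taken; }
  occ.attr("dim") = vol.attr("dim");
  return occ;
}

// Full smoothing loop (blur + exact-count rethreshold) without R round
// trips; semantics identical to iterating the two exported kernels.
// [[Rcpp::export(name = ".smooth_loop_cpp")]]
IntegerVector smooth_loop_cpp(IntegerVector occ, int nx, int ny, int nz,
                              double sigma, int n_iter, int n_solid) {
  IntegerVector cur = clone(occ);
  for (int it = 0; it < n_iter; ++it) {
    NumericVector f(cur.size());
    for (int q = 0; q < cur.size(); ++q) f[q] = cur[q];
    NumericVector b = gaussian_blur3_cpp(f, nx, ny, nz, sigma);
    cur = threshold_to_count_cpp(b, n_solid);
  }
  cur.attr("dim") = IntegerVector::create(nx, ny, nz);
  return cur;
}

// Felzenszwalb-Huttenlocher exact squared EDT of the complement of `occ`
// (distance from phase voxels to the nearest background voxel), in voxels^2.
namespace {
void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = R_NegInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector occ, int nx, int ny, int nz) {
  const double BIG = 1e18;
  std::vector<double> d(nx * (size_t)ny * nz);
  for (size_t i = 0; i < d.size(); ++i) d[i] = occ[i] ? BIG : 0.0;
  std::vector<double> f(std::max({nx, ny, nz})), o(std::max({nx, ny, nz}));
  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[idx3(i, j, k, nx, ny)];
      edt1d(f, o, nx);
      for (int i = 0; i < nx; ++i) d[idx3(i, j, k, nx, ny)] = o[i];
    }
  // y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx3(i, j, k, nx, ny)];
      edt1d(f, o, ny);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = o[j];
    }
  // z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx3(i, j, k, nx, ny)];
      edt1d(f, o, nz);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = o[k];
    }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Local thickness (Hildebrand-Ruegsegger): thickness(q) = diameter of the
// largest inscribed sphere (centred anywhere in the phase) that contains q.
// Sphere painting over the EDT field, largest radii first.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(IntegerVector occ, int nx, int ny, int nz) {
  NumericVector ed = edt_sq_cpp(occ, nx, ny, nz);
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> rad(n);
  std::vector<int> ord;
  ord.reserve(n / 4);
  for (size_t i = 0; i < n; ++i) {
    rad[i] = occ[i] ? std::sqrt(ed[i]) : 0.0;
    if (occ[i]) ord.push_back((int)i);
  }
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return rad[a] > rad[b]; });
  std::vector<double> th(n, 0.0);
  for (int c : ord) {
    const double r = rad[c], dia = 2.0 * r;
    const int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
    const int ir = (int)std::floor(r);
    for (int dk = -ir; dk <= ir; ++dk) {
      const int k = ck + dk;
      if (k < 0 || k >= nz) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        const int j = cj + dj;
        if (j < 0 || j >= ny) continue;
        const double rem2 = r * r - dk * dk - dj * dj;
        if (rem2 < 0) continue;
        const int di_max = (int)std::floor(std::sqrt(rem2));
        for (int di = -di_max; di <= di_max; ++di) {
          const int i = ci + di;
          if (i < 0 || i >= nx) continue;
          const int q = idx3(i, j, k, nx, ny);
          if (th[q] < dia) th[q] = dia;
        }
      }
    }
  }
  NumericVector out(th.begin(), th.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// 6-connected component labelling (labels 1..ncomp by discovery order, scan
// order ascending linear index so labelling is deterministic).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector occ, int nx, int ny, int nz) {
  IntegerVector lab(nx * ny * nz, 0);
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < occ.size(); ++s) {
    if (!occ[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const int c = stack.back();
      stack.pop_back();
      const int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const int q = idx3(ii, jj, kk, nx, ny);
        if (occ[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// Mean intercept length scan: for each direction, parallel test lines on a
// plane through the volume centre are marched with a sub-voxel step;
// nearest-voxel sampling.  Returns per-direction total solid length and
// number of solid runs (intercepts).
// [[Rcpp::export(name = ".mil_scan_cpp")]]
List mil_scan_cpp(IntegerVector occ, int nx, int ny, int nz,
                  NumericMatrix dirs, double line_spacing, double step,
                  NumericVector jitter) {
  const int nd = dirs.nrow();
  NumericVector solid_len(nd), n_runs(nd), total_len(nd);
  const double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;
  const double R = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny +
                                   (double)nz * nz);
  for (int d = 0; d < nd; ++d) {
    double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
    // orthonormal basis (e1, e2) perpendicular to u
    double ax = 1, ay = 0, az = 0;
    if (std::fabs(ux) > 0.9) { ax = 0; ay = 1; }
    double e1x = uy * az - uz * ay, e1y = uz * ax - ux * az,
           e1z = ux * ay - uy * ax;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z,
           e2z = ux * e1y - uy * e1x;
    const double j1 = jitter[(2 * d) % jitter.size()] * line_spacing;
    const double j2 = jitter[(2 * d + 1) % jitter.size()] * line_spacing;
    double sl = 0.0, runs = 0.0, tl = 0.0;
    for (double a = -R + j1; a <= R; a += line_spacing)
      for (double b = -R + j2; b <= R; b += line_spacing) {
        const double ox = cx + a * e1x + b * e2x, oy = cy + a * e1y + b * e2y,
                     oz = cz + a * e1z + b * e2z;
        int prev = 0;
        bool entered = false;
        for (double t = -R; t <= R; t += step) {
          const int i = (int)std::floor(ox + t * ux);
          const int j = (int)std::floor(oy + t * uy);
          const int k = (int)std::floor(oz + t * uz);
          int cur = 0;
          bool inside = (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz);
          if (inside) {
            cur = occ[idx3(i, j, k, nx, ny)];
            tl += step;
          }
          if (cur) sl += step;
          if (cur && !prev) runs += 1.0;
          prev = cur;
          (void)entered;
        }
      }
    solid_len[d] = sl;
    n_runs[d] = runs;
    total_len[d] = tl;
  }
  return List::create(_["solid_len"] = solid_len, _["n_runs"] = n_runs,
                      _["total_len"] = total_len);
}
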