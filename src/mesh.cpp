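#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// subdivision of each grid cube.  The subdivision shares the same main
// diagonal in every cube, so faces between neighbouring cubes are split
// consistently and the extracted surface is watertight when the field is
// below the level on the array boundary (the R wrapper zero-pads).
// Vertices are interpolated on tetrahedron edges and shared through an
// edge-keyed map; triangle orientation is fixed so normals point from the
// solid (field > level) to the void side.

namespace {

struct V3 { double x, y, z; };
inline V3 vsub(const V3& a, const V3& b) { return V3{a.x-b.x, a.y-b.y, a.z-b.z}; }
inline V3 vcross(const V3& a, const V3& b) {
  return V3{a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double vdot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

}  // namespace

// [[Rcpp::export(name = ".marching_tets_cpp")]]
List marching_tets_cpp(NumericVector field, int nx, int ny, int nz,
                       double level) {
  // grid points at voxel centres, indices 0..nx-1 etc.
  auto fidx = [&](int i, int j, int k) { return i + nx * (j + (size_t)ny * k); };

  std::map<std::pair<long long, long long>, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based vertex ids, triples

  auto vert_on_edge = [&](long long ga, long long gb, double fa, double fb,
                          V3 pa, V3 pb) -> int {
    if (ga > gb) { std::swap(ga, gb); std::swap(fa, fb); std::swap(pa, pb); }
    auto key = std::make_pair(ga, gb);
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    t = std::min(1.0, std::max(0.0, t));
    vx.push_back(pa.x + t * (pb.x - pa.x));
    vy.push_back(pa.y + t * (pb.y - pa.y));
    vz.push_back(pa.z + t * (pb.z - pa.z));
    const int id = (int)vx.size() - 1;
    edge_vert[key] = id;
    return id;
  };

  // Kuhn: 6 tets around diagonal c000 -> c111, via axis permutations
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

  auto emit_tri = [&](int a, int b, int c, const V3& inside_ref) {
    // orient so the normal points away from the solid reference point
    V3 p1{vx[a], vy[a], vz[a]}, p2{vx[b], vy[b], vz[b]}, p3{vx[c], vy[c], vz[c]};
    V3 n = vcross(vsub(p2, p1), vsub(p3, p1));
    V3 cen{(p1.x+p2.x+p3.x)/3.0, (p1.y+p2.y+p3.y)/3.0, (p1.z+p2.z+p3.z)/3.0};
    if (vdot(n, vsub(cen, inside_ref)) < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        for (int p = 0; p < 6; ++p) {
          int off[4][3];
          off[0][0] = 0; off[0][1] = 0; off[0][2] = 0;
          for (int v = 1; v < 4; ++v) {
            for (int c = 0; c < 3; ++c) off[v][c] = off[v - 1][c];
            off[v][perms[p][v - 1]] = 1;
          }
          long long gid[4];
          double fv[4];
          V3 pos[4];
          int inside[4], n_in = 0;
          for (int v = 0; v < 4; ++v) {
            const int ii = i + off[v][0], jj = j + off[v][1], kk = k + off[v][2];
            gid[v] = (long long)fidx(ii, jj, kk);
            fv[v] = field[gid[v]];
            pos[v] = V3{(double)ii, (double)jj, (double)kk};
            inside[v] = fv[v] > level;
            n_in += inside[v];
          }
          if (n_in == 0 || n_in == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) (inside[v] ? ins[ni++] : outs[no++]) = v;
          if (n_in == 1) {
            const int a = ins[0];
            int e[3];
            for (int t = 0; t < 3; ++t)
              e[t] = vert_on_edge(gid[a], gid[outs[t]], fv[a], fv[outs[t]],
                                  pos[a], pos[outs[t]]);
            emit_tri(e[0], e[1], e[2], pos[a]);
          } else if (n_in == 3) {
            const int a = outs[0];
            int e[3];
            for (int t = 0; t < 3; ++t)
              e[t] = vert_on_edge(gid[ins[t]], gid[a], fv[ins[t]], fv[a],
                                  pos[ins[t]], pos[a]);
            V3 cen{(pos[ins[0]].x + pos[ins[1]].x + pos[ins[2]].x) / 3.0,
                   (pos[ins[0]].y + pos[ins[1]].y + pos[ins[2]].y) / 3.0,
                   (pos[ins[0]].z + pos[ins[1]].z + pos[ins[2]].z) / 3.0};
            emit_tri(e[0], e[1], e[2], cen);
          } else {  // 2 in, 2 out: quad split into two triangles
            const int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            const int eac = vert_on_edge(gid[a], gid[c], fv[a], fv[c], pos[a], pos[c]);
            const int ead = vert_on_edge(gid[a], gid[d], fv[a], fv[d], pos[a], pos[d]);
            const int ebc = vert_on_edge(gid[b], gid[c], fv[b], fv[c], pos[b], pos[c]);
            const int ebd = vert_on_edge(gid[b], gid[d], fv[b], fv[d], pos[b], pos[d]);
            V3 cen{(pos[a].x + pos[b].x) / 2.0, (pos[a].y + pos[b].y) / 2.0,
                   (pos[a].z + pos[b].z) / 2.0};
            emit_tri(eac, ead, ebd, cen);
            emit_tri(eac, ebd, ebc, cen);
          }
        }
      }

  const int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; ++q) { V(q,0) = vx[q]; V(q,1) = vy[q]; V(q,2) = vz[q]; }
  IntegerMatrix F(nf, 3);
  for (int q = 0; q < nf; ++q) {
    F(q,0) = tri[3*q] + 1; F(q,1) = tri[3*q+1] + 1; F(q,2) = tri[3*q+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Per-vertex angle deficit (2*pi - sum of incident angles) and one-third
// barycentric vertex area; Gaussian curvature = deficit / area (discrete
// Gauss-Bonnet).  Also returns the cotangent-Laplacian mean-curvature-normal
// magnitude for principal-curvature recovery.
// [[Rcpp::export(name = ".mesh_curvature_cpp")]]
List mesh_curvature_cpp(NumericMatrix V, IntegerMatrix F) {
  const int nv = V.nrow(), nf = F.nrow();
  NumericVector deficit(nv, 2.0 * M_PI), area(nv, 0.0);
  NumericVector hnx(nv, 0.0), hny(nv, 0.0), hnz(nv, 0.0);
  NumericVector nxsum(nv, 0.0), nysum(nv, 0.0), nzsum(nv, 0.0);
  for (int f = 0; f < nf; ++f) {
    const int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    V3 pa{V(a,0), V(a,1), V(a,2)}, pb{V(b,0), V(b,1), V(b,2)},
       pc{V(c,0), V(c,1), V(c,2)};
    V3 ab = vsub(pb, pa), ac = vsub(pc, pa), bc = vsub(pc, pb);
    const double la = vdot(bc, bc), lb = vdot(ac, ac), lc = vdot(ab, ab);
    V3 nrm = vcross(ab, ac);
    const double a2 = std::sqrt(vdot(nrm, nrm));
    const double fa = 0.5 * a2;
    if (fa <= 0) continue;
    auto ang = [](double opp2, double s1, double s2) {
      double cosv = (s1 + s2 - opp2) / (2.0 * std::sqrt(s1 * s2));
      cosv = std::min(1.0, std::max(-1.0, cosv));
      return std::acos(cosv);
    };
    const double A = ang(la, lb, lc), B = ang(lb, la, lc), C = ang(lc, la, lb);
    deficit[a] -= A; deficit[b] -= B; deficit[c] -= C;
    area[a] += fa / 3.0; area[b] += fa / 3.0; area[c] += fa / 3.0;
    // cotangent mean-curvature contributions
    const double cotA = std::cos(A) / std::max(std::sin(A), 1e-12);
    const double cotB = std::cos(B) / std::max(std::sin(B), 1e-12);
    const double cotC = std::cos(C) / std::max(std::sin(C), 1e-12);
    // edge (b,c) opposite A etc.
    hnx[b] += cotA * (V(c,0)-V(b,0)); hny[b] += cotA * (V(c,1)-V(b,1)); hnz[b] += cotA * (V(c,2)-V(b,2));
    hnx[c] += cotA * (V(b,0)-V(c,0)); hny[c] += cotA * (V(b,1)-V(c,1)); hnz[c] += cotA * (V(b,2)-V(c,2));
    hnx[a] += cotB * (V(c,0)-V(a,0)); hny[a] += cotB * (V(c,1)-V(a,1)); hnz[a] += cotB * (V(c,2)-V(a,2));
    hnx[c] += cotB * (V(a,0)-V(c,0)); hny[c] += cotB * (V(a,1)-V(c,1)); hnz[c] += cotB * (V(a,2)-V(c,2));
    hnx[a] += cotC * (V(b,0)-V(a,0)); hny[a] += cotC * (V(b,1)-V(a,1)); hnz[a] += cotC * (V(b,2)-V(a,2));
    hnx[b] += cotC * (V(a,0)-V(b,0)); hny[b] += cotC * (V(a,1)-V(b,1)); hnz[b] += cotC * (V(a,2)-V(b,2));
    // area-weighted vertex normals (for the sign of H)
    nxsum[a] += nrm.x; nysum[a] += nrm.y; nzsum[a] += nrm.z;
    nxsum[b] += nrm.x; nysum[b] += nrm.y; nzsum[b] += nrm.z;
    nxsum[c] += nrm.x; nysum[c] += nrm.y; nzsum[c] += nrm.z;
  }
  NumericVector K(nv), H(nv);
  for (int q = 0; q < nv; ++q) {
    K[q] = (area[q] > 0) ? deficit[q] / area[q] : 0.0;
    // mean curvature normal: (1/(2A)) * sum cot * e ; H = 0.5 |.| with sign
    const double mx = hnx[q] / (4.0 * std::max(area[q], 1e-12));
    const double my = hny[q] / (4.0 * std::max(area[q], 1e-12));
    const double mz = hnz[q] / (4.0 * std::max(area[q], 1e-12));
    double h = std::sqrt(mx * mx + my * my + mz * mz);
    // cot-Laplacian points along -H n for outward n; sign from vertex normal
    if (mx * nxsum[q] + my * nysum[q] + mz * nzsum[q] > 0) h = -h;
    H[q] = h;
  }
  return List::create(_["K"] = K, _["H"] = H, _["deficit"] = deficit,
                      _["area"] = area);
}

// Total surface area and signed enclosed volume (divergence theorem).
// [[Rcpp::export(name = ".mesh_area_volume_cpp")]]
NumericVector mesh_area_volume_cpp(NumericMatrix V, IntegerMatrix F) {
  double area = 0.0, vol = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    const int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    V3 pa{V(a,0), V(a,1), V(a,2)}, pb{V(b,0), V(b,1), V(b,2)},
       pc{V(c,0), V(c,1), V(c,2)};
    V3 n = vcross(vsub(pb, pa), vsub(pc, pa));
    area += 0.5 * std::sqrt(vdot(n, n));
    vol += vdot(pa, vcross(pb, pc)) / 6.0;
  }
  return NumericVector::create(area, vol);
}
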