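#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Bounded Voronoi edge network by per-cell half-space enumeration.
//
// For each seed the Voronoi cell is the intersection of the bisector
// half-spaces against its neighbours.  Candidate cell vertices are the
// feasible intersections of plane triples; each candidate is then validated
// globally (a true Voronoi vertex is no closer to any seed than to its own),
// which makes the k-nearest-neighbour truncation of the plane set safe.
// Degenerate vertices where more than three bisectors meet (e.g. seeds on a
// regular lattice) are merged by coordinate clustering, and cell edges are
// recovered per plane pair as the extreme pair of vertices along the
// intersection line of the two planes.

namespace {

struct Vec3 {
  double x, y, z;
};

inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Plane {
  Vec3 n;     // unit normal
  double d;   // n . x <= d inside the cell
};

// Solve the 3x3 system n_a.x = d_a etc. by Cramer's rule.
bool solve3(const Plane& a, const Plane& b, const Plane& c, Vec3& out) {
  const double det = dot(a.n, cross(b.n, c.n));
  if (std::fabs(det) < 1e-10) return false;  // unit normals: det is scale-free
  Vec3 t1 = cross(b.n, c.n), t2 = cross(c.n, a.n), t3 = cross(a.n, b.n);
  out.x = (a.d * t1.x + b.d * t2.x + c.d * t3.x) / det;
  out.y = (a.d * t1.y + b.d * t2.y + c.d * t3.y) / det;
  out.z = (a.d * t1.z + b.d * t2.z + c.d * t3.z) / det;
  return true;
}

}  // namespace

// `seeds` may contain ghost rows (e.g. mirrored seeds bounding the
// tessellation at the domain faces); cells are built only for the first
// `n_cells` rows, but every row participates in the bisector planes and in
// the global vertex validation.
// [[Rcpp::export(name = ".voronoi_edges_cpp")]]
List voronoi_edges_cpp(NumericMatrix seeds, double L, int k_neighbors,
                       int n_cells) {
  const int n = seeds.nrow();
  if (n < 2) stop("need at least 2 seeds");
  if (n_cells < 1 || n_cells > n) stop("invalid n_cells");
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = Vec3{seeds(i, 0), seeds(i, 1), seeds(i, 2)};

  const double eps_feas = 1e-7 * L;   // half-space feasibility slack
  const double eps_act  = 1e-6 * L;   // plane considered active at a vertex
  const double eps_glob = 1e-7 * L;   // global nearest-seed validation slack
  const double tol_merge = 1e-5 * L;  // vertex clustering tolerance

  std::vector<std::array<double, 6>> raw_edges;  // x1 y1 z1 x2 y2 z2
  std::vector<int> raw_cell;                     // emitting cell per raw edge

  const int k = std::min(n - 1, k_neighbors);
  std::vector<std::pair<double, int>> dist_idx(n);

  for (int i = 0; i < n_cells; ++i) {
    for (int j = 0; j < n; ++j)
      dist_idx[j] = {dot(sub(P[j], P[i]), sub(P[j], P[i])), j};
    dist_idx[i].first = R_PosInf;
    std::partial_sort(dist_idx.begin(), dist_idx.begin() + k, dist_idx.end());

    std::vector<Plane> pl(k);
    for (int m = 0; m < k; ++m) {
      const int j = dist_idx[m].second;
      Vec3 u = sub(P[j], P[i]);
      const double nu = norm(u);
      u.x /= nu; u.y /= nu; u.z /= nu;
      Vec3 mid{0.5 * (P[i].x + P[j].x), 0.5 * (P[i].y + P[j].y),
               0.5 * (P[i].z + P[j].z)};
      pl[m] = Plane{u, dot(u, mid)};
    }

    // candidate vertices: feasible + globally validated triple intersections
    std::vector<Vec3> verts;
    std::vector<std::vector<int>> active;  // planes active at each cluster
    for (int a = 0; a < k - 2; ++a)
      for (int b = a + 1; b < k - 1; ++b)
        for (int c = b + 1; c < k; ++c) {
          Vec3 x;
          if (!solve3(pl[a], pl[b], pl[c], x)) continue;
          bool ok = true;
          for (int m = 0; m < k && ok; ++m)
            if (dot(pl[m].n, x) - pl[m].d > eps_feas) ok = false;
          if (!ok) continue;
          // global check: no seed strictly closer than the owner seed
          const double di = norm(sub(x, P[i]));
          for (int m = 0; m < n && ok; ++m) {
            if (m == i) continue;
            if (di - norm(sub(x, P[m])) > eps_glob) ok = false;
          }
          if (!ok) continue;
          // merge into clusters
          int ci = -1;
          for (size_t q = 0; q < verts.size(); ++q)
            if (norm(sub(x, verts[q])) < tol_merge) { ci = (int)q; break; }
          if (ci < 0) {
            verts.push_back(x);
            active.push_back({});
            ci = (int)verts.size() - 1;
          }
          for (int m = 0; m < k; ++m)
            if (std::fabs(dot(pl[m].n, verts[ci]) - pl[m].d) <= eps_act) {
              std::vector<int>& av = active[ci];
              if (std::find(av.begin(), av.end(), m) == av.end())
                av.push_back(m);
            }
        }

    // edges of the (convex) cell: per plane pair, extreme vertices on the line
    const int nv = (int)verts.size();
    if (nv < 2) continue;
    for (int a = 0; a < k - 1; ++a)
      for (int b = a + 1; b < k; ++b) {
        Vec3 t = cross(pl[a].n, pl[b].n);
        const double tn = norm(t);
        if (tn < 1e-10) continue;
        int imin = -1, imax = -1;
        double smin = R_PosInf, smax = R_NegInf;
        for (int q = 0; q < nv; ++q) {
          const std::vector<int>& av = active[q];
          if (std::find(av.begin(), av.end(), a) == av.end()) continue;
          if (std::find(av.begin(), av.end(), b) == av.end()) continue;
          const double s = dot(t, verts[q]) / tn;
          if (s < smin) { smin = s; imin = q; }
          if (s > smax) { smax = s; imax = q; }
        }
        if (imin < 0 || imax < 0 || imin == imax) continue;
        if (smax - smin < tol_merge) continue;
        raw_edges.push_back({verts[imin].x, verts[imin].y, verts[imin].z,
                             verts[imax].x, verts[imax].y, verts[imax].z});
        raw_cell.push_back(i);
      }
  }

  // global node merge via spatial hash (cell size tol_merge), then edge dedup
  const double h = std::max(tol_merge, 1e-12);
  std::map<std::array<long long, 3>, std::vector<int>> grid;
  std::vector<Vec3> nodes;
  auto node_id = [&](const Vec3& v) -> int {
    const long long gx = (long long)std::floor(v.x / h);
    const long long gy = (long long)std::floor(v.y / h);
    const long long gz = (long long)std::floor(v.z / h);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = grid.find({gx + dx, gy + dy, gz + dz});
          if (it == grid.end()) continue;
          for (int id : it->second)
            if (norm(sub(v, nodes[id])) < tol_merge) return id;
        }
    nodes.push_back(v);
    grid[{gx, gy, gz}].push_back((int)nodes.size() - 1);
    return (int)nodes.size() - 1;
  };

  // multiplicity = number of distinct cells bordering the edge (a cell can
  // emit the same edge from several plane pairs when mirror degeneracies
  // put more than two active planes on it)
  std::map<std::pair<int, int>, int> seen;  // edge key -> index
  std::vector<std::pair<int, int>> edges;
  std::vector<int> mult;
  std::vector<int> last_cell;
  for (size_t t = 0; t < raw_edges.size(); ++t) {
    auto& e = raw_edges[t];
    int u = node_id(Vec3{e[0], e[1], e[2]});
    int v = node_id(Vec3{e[3], e[4], e[5]});
    if (u == v) continue;
    std::pair<int, int> key{std::min(u, v), std::max(u, v)};
    auto it = seen.find(key);
    if (it != seen.end()) {
      if (last_cell[it->second] != raw_cell[t]) {
        ++mult[it->second];
        last_cell[it->second] = raw_cell[t];
      }
      continue;
    }
    seen[key] = (int)edges.size();
    edges.push_back(key);
    mult.push_back(1);
    last_cell.push_back(raw_cell[t]);
  }

  NumericMatrix nm((int)nodes.size(), 3);
  for (size_t q = 0; q < nodes.size(); ++q) {
    nm(q, 0) = nodes[q].x; nm(q, 1) = nodes[q].y; nm(q, 2) = nodes[q].z;
  }
  IntegerMatrix em((int)edges.size(), 2);
  IntegerVector mv((int)edges.size());
  for (size_t q = 0; q < edges.size(); ++q) {
    em(q, 0) = edges[q].first + 1;  // 1-based for R
    em(q, 1) = edges[q].second + 1;
    mv[q] = mult[q];
  }
  return List::create(_["nodes"] = nm, _["edges"] = em,
                      _["multiplicity"] = mv);
}
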