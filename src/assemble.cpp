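#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Triplet assembly of the global stiffness on the free dofs for sparse
// direct factorization: returns the upper triangle of K_ff and the
// right-hand sides -K_fb u_b for a set of affine boundary-value cases.
// dof numbering: 3 * active_node + component (0-based), as in elastic.cpp.

// [[Rcpp::export(name = ".fem_assemble_cpp")]]
List fem_assemble_cpp(IntegerMatrix edofs, NumericMatrix Ke,
                      IntegerVector free_map, NumericMatrix ub_cases,
                      int nfree) {
  // free_map: ndof-long, 0-based index into free dofs, -1 if constrained
  // ub_cases: ndof x ncase prescribed values (0 at free dofs)
  const int ne = edofs.nrow(), ncase = ub_cases.ncol();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * 300);
  tj.reserve((size_t)ne * 300);
  tx.reserve((size_t)ne * 300);
  NumericMatrix rhs(nfree, ncase);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 24; ++a) {
      const int ga = edofs(e, a);
      const int fa = free_map[ga];
      for (int b = 0; b < 24; ++b) {
        const int gb = edofs(e, b);
        const int fb = free_map[gb];
        const double v = Ke(a, b);
        if (fa >= 0 && fb >= 0) {
          if (fa <= fb) {  // upper triangle
            ti.push_back(fa + 1);
            tj.push_back(fb + 1);
            tx.push_back(v);
          }
        } else if (fa >= 0 && fb < 0) {
          for (int c = 0; c < ncase; ++c)
            rhs(fa, c) -= v * ub_cases(gb, c);
        }
      }
    }
  }
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()),
                      _["rhs"] = rhs);
}

// element dof table for the active-node numbering (helper shared with the
// R-side assembly path)
// [[Rcpp::export(name = ".fem_edofs_cpp")]]
IntegerMatrix fem_edofs_cpp(IntegerVector occ, int nx, int ny, int nz) {
  const int NX = nx + 1, NY = ny + 1;
  std::vector<int> node_map((size_t)NX * NY * (nz + 1), -1);
  std::vector<int> elems;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (occ[i + nx * (j + (size_t)ny * k)]) {
          elems.push_back(i + nx * (j + ny * k));
          for (int a = 0; a < 8; ++a)
            node_map[(i + (a & 1)) +
                     NX * ((j + ((a >> 1) & 1)) +
                           (size_t)NY * (k + ((a >> 2) & 1)))] = 0;
        }
  int nn = 0;
  for (auto& m : node_map)
    if (m == 0) m = nn++;
    else m = -1;
  IntegerMatrix edofs((int)elems.size(), 24);
  for (size_t e = 0; e < elems.size(); ++e) {
    const int c = elems[e];
    const int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    for (int a = 0; a < 8; ++a) {
      const int an = node_map[(i + (a & 1)) +
                              NX * ((j + ((a >> 1) & 1)) +
                                    (size_t)NY * (k + ((a >> 2) & 1)))];
      for (int d = 0; d < 3; ++d) edofs(e, 3 * a + d) = 3 * an + d;
    }
  }
  return edofs;
}
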