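// Match unit directions to spherical triangles with barycentric weights.
// Candidate faces per query come from a CSR list built around the nearest
// sphere vertex (2-ring); the accepted face maximises the minimum barycentric
// coordinate (ties: smallest face index), giving a deterministic assignment.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_sphere_bary")]]
List cpp_sphere_bary(NumericMatrix dirs, IntegerVector nn_vertex,
                     NumericMatrix verts, IntegerMatrix faces,
                     IntegerVector cand_ptr, IntegerVector cand_idx) {
  const int n = dirs.nrow();
  IntegerVector face_id(n);
  NumericMatrix mu(n, 3);
  IntegerVector fallback(n);
  for (int q = 0; q < n; ++q) {
    double d0 = dirs(q, 0), d1 = dirs(q, 1), d2 = dirs(q, 2);
    int vtx = nn_vertex[q] - 1;
    double bestmin = -1e30;
    int bestf = -1;
    double bm0 = 0, bm1 = 0, bm2 = 0;
    for (int c = cand_ptr[vtx]; c < cand_ptr[vtx + 1]; ++c) {
      int fi = cand_idx[c] - 1;
      int a = faces(fi, 0) - 1, b = faces(fi, 1) - 1, cc = faces(fi, 2) - 1;
      // solve [A B C] m = dir (3x3 linear system, Cramer)
      double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
      double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
      double cx = verts(cc, 0), cy = verts(cc, 1), cz = verts(cc, 2);
      double det = ax * (by * cz - bz * cy) - bx * (ay * cz - az * cy) +
                   cx * (ay * bz - az * by);
      if (std::abs(det) < 1e-14) continue;
      double m0 = (d0 * (by * cz - bz * cy) - bx * (d1 * cz - d2 * cy) +
                   cx * (d1 * bz - d2 * by)) / det;
      double m1 = (ax * (d1 * cz - d2 * cy) - d0 * (ay * cz - az * cy) +
                   cx * (ay * d2 - az * d1)) / det;
      double m2 = (ax * (by * d2 - bz * d1) - bx * (ay * d2 - az * d1) +
                   d0 * (ay * bz - az * by)) / det;
      double s = m0 + m1 + m2;
      if (std::abs(s) < 1e-14) continue;
      m0 /= s; m1 /= s; m2 /= s;
      double mn = std::min(m0, std::min(m1, m2));
      if (mn > bestmin + 1e-15) {
        bestmin = mn;
        bestf = fi;
        bm0 = m0; bm1 = m1; bm2 = m2;
      }
    }
    if (bestf < 0) {
      face_id[q] = NA_INTEGER;
      continue;
    }
    if (bestmin < -1e-9) fallback[q] = 1;  // no containing face; nearest used
    // clamp and renormalize
    bm0 = std::max(bm0, 0.0); bm1 = std::max(bm1, 0.0); bm2 = std::max(bm2, 0.0);
    double s = bm0 + bm1 + bm2;
    face_id[q] = bestf + 1;
    mu(q, 0) = bm0 / s; mu(q, 1) = bm1 / s; mu(q, 2) = bm2 / s;
  }
  return List::create(_["face"] = face_id, _["mu"] = mu,
                      _["fallback"] = fallback);
}
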