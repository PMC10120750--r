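// Classic marching cubes on a scalar volume (column-major, dim = c(nx,ny,nz)).
// Produces a vertex-deduplicated triangle mesh; triangle winding is chosen so
// that for a volume with interior > isovalue the face normals point outward.

#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include "mc_tables.h"
using namespace Rcpp;

// cube corner offsets (Bourke convention)
static const int cornerOff[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};
// the 12 edges as corner pairs
static const int edgeCorner[12][2] = {
  {0, 1}, {1, 2}, {2, 3}, {3, 0},
  {4, 5}, {5, 6}, {6, 7}, {7, 4},
  {0, 4}, {1, 5}, {2, 6}, {3, 7}
};

// [[Rcpp::export(name = ".cpp_marching_cubes")]]
List cpp_marching_cubes(NumericVector vol, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto at = [&](int i, int j, int k) {
    return vol[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<long long, int> edgeMap; // edge key -> vertex id (0-based)

  auto edgeKey = [&](int i, int j, int k, int axis) {
    long long lin = (long long)i + (long long)nx * (j + (long long)ny * k);
    return lin * 3 + axis;
  };
  auto vertOnEdge = [&](int ci, int cj, int ck, int e) {
    int a = edgeCorner[e][0], b = edgeCorner[e][1];
    int ia = ci + cornerOff[a][0], ja = cj + cornerOff[a][1], ka = ck + cornerOff[a][2];
    int ib = ci + cornerOff[b][0], jb = cj + cornerOff[b][1], kb = ck + cornerOff[b][2];
    int axis = (ia != ib) ? 0 : (ja != jb) ? 1 : 2;
    int mi = std::min(ia, ib), mj = std::min(ja, jb), mk = std::min(ka, kb);
    long long key = edgeKey(mi, mj, mk, axis);
    auto it = edgeMap.find(key);
    if (it != edgeMap.end()) return it->second;
    double va = at(ia, ja, ka), vb = at(ib, jb, kb);
    double t = (std::abs(vb - va) < 1e-12) ? 0.5 : (iso - va) / (vb - va);
    t = std::min(1.0, std::max(0.0, t));
    vx.push_back(ia + t * (ib - ia));
    vy.push_back(ja + t * (jb - ja));
    vz.push_back(ka + t * (kb - ka));
    int id = (int)vx.size() - 1;
    edgeMap[key] = id;
    return id;
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int cubeindex = 0;
        for (int c = 0; c < 8; ++c)
          if (at(i + cornerOff[c][0], j + cornerOff[c][1], k + cornerOff[c][2]) > iso)
            cubeindex |= (1 << c);
        if (edgeTable[cubeindex] == 0) continue;
        for (int t = 0; triTable[cubeindex][t] != -1; t += 3) {
          int v0 = vertOnEdge(i, j, k, triTable[cubeindex][t]);
          int v1 = vertOnEdge(i, j, k, triTable[cubeindex][t + 1]);
          int v2 = vertOnEdge(i, j, k, triTable[cubeindex][t + 2]);
          if (v0 == v1 || v1 == v2 || v0 == v2) continue; // degenerate
          tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
        }
      }

  int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = tri[3 * f] + 1; F(f, 1) = tri[3 * f + 1] + 1; F(f, 2) = tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
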