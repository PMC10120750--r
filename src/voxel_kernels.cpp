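// Voxel-level kernels: exact Euclidean distance transform, flood fill,
// trilinear interpolation, brute/grid nearest-neighbour queries.
// Volumes are passed as numeric vectors with dim = c(nx, ny, nz), R column-major:
// index = i + nx*(j + ny*k), 0-based here.

#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + sq(q)) - (f[v[k]] + sq(v[k]))) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + sq(q)) - (f[v[k]] + sq(v[k]))) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = sq(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(NumericVector binary, IntegerVector dims) {
  // Distance (Euclidean, voxels) from each voxel to the nearest foreground (!=0) voxel.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e18;
  NumericVector out(binary.size());
  // init: 0 at foreground, INF elsewhere
  for (R_xlen_t i = 0; i < binary.size(); ++i) out[i] = binary[i] != 0 ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)nx * ny * k];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)nx * ny * k] = std::sqrt(d[k]);
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_flood_background")]]
LogicalVector cpp_flood_background(NumericVector binary, IntegerVector dims) {
  // 6-connected flood fill of the background (0) starting from all boundary voxels.
  // Returns TRUE for background voxels reachable from the volume border.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector vis(binary.size());
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) { return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (!vis[id] && binary[id] == 0) { vis[id] = true; q.push(id); }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { push(i, j, 0); push(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { push(i, 0, k); push(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { push(0, j, k); push(nx - 1, j, k); }
  while (!q.empty()) {
    R_xlen_t id = q.front(); q.pop();
    int i = id % nx, j = (id / nx) % ny, k = id / ((R_xlen_t)nx * ny);
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  return vis;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(NumericVector binary, IntegerVector dims) {
  // 6-connected component labelling of foreground (!=0); labels 1..n, 0 background.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(binary.size());
  int cur = 0;
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) { return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); };
  for (R_xlen_t s = 0; s < binary.size(); ++s) {
    if (binary[s] == 0 || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t id = q.front(); q.pop();
      int i = id % nx, j = (id / nx) % ny, k = id / ((R_xlen_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t id2 = idx(ii, jj, kk);
        if (binary[id2] != 0 && lab[id2] == 0) { lab[id2] = cur; q.push(id2); }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".cpp_trilinear")]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims, NumericMatrix pts,
                            double fill) {
  // Sample vol at 0-based continuous coordinates pts (n x 3, columns x,y,z).
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z) ||
        x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    auto at = [&](int i, int j, int k) { return vol[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)]; };
    double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
    double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
    double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
    double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
    out[p] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_nn_index")]]
List cpp_nn_index(NumericMatrix query, NumericMatrix ref) {
  // For each query point, index (1-based) and distance of nearest reference point.
  // Uniform-grid spatial hash; falls back to brute force for tiny references.
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  if (nr == 0) stop("empty reference point set");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref(i, d));
      hi[d] = std::max(hi[d], ref(i, d));
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  int ncell = std::max(1, (int)std::floor(std::cbrt((double)nr / 2.0)));
  ncell = std::min(ncell, 64);
  double h = ext / ncell + 1e-12;
  int gx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
  int gy = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
  int gz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
  std::vector<std::vector<int> > cells((R_xlen_t)gx * gy * gz);
  auto cellof = [&](double x, double y, double z) {
    int ci = std::min(gx - 1, std::max(0, (int)((x - lo[0]) / h)));
    int cj = std::min(gy - 1, std::max(0, (int)((y - lo[1]) / h)));
    int ck = std::min(gz - 1, std::max(0, (int)((z - lo[2]) / h)));
    return std::make_tuple(ci, cj, ck);
  };
  for (int i = 0; i < nr; ++i) {
    auto c = cellof(ref(i, 0), ref(i, 1), ref(i, 2));
    cells[std::get<0>(c) + (R_xlen_t)gx * (std::get<1>(c) + (R_xlen_t)gy * std::get<2>(c))].push_back(i);
  }
  for (int p = 0; p < nq; ++p) {
    double qx = query(p, 0), qy = query(p, 1), qz = query(p, 2);
    auto c = cellof(qx, qy, qz);
    int ci = std::get<0>(c), cj = std::get<1>(c), ck = std::get<2>(c);
    double best = R_PosInf;
    int bestI = -1;
    for (int ring = 0; ring < std::max({gx, gy, gz}); ++ring) {
      // search cells at Chebyshev distance == ring
      bool any = false;
      for (int dk = -ring; dk <= ring; ++dk)
        for (int dj = -ring; dj <= ring; ++dj)
          for (int di = -ring; di <= ring; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != ring) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || ii >= gx || jj < 0 || jj >= gy || kk < 0 || kk >= gz) continue;
            any = true;
            const std::vector<int>& cell = cells[ii + (R_xlen_t)gx * (jj + (R_xlen_t)gy * kk)];
            for (size_t t = 0; t < cell.size(); ++t) {
              int i = cell[t];
              double d2 = sq(qx - ref(i, 0)) + sq(qy - ref(i, 1)) + sq(qz - ref(i, 2));
              if (d2 < best) { best = d2; bestI = i; }
            }
          }
      // stop once a neighbour is found and the next ring cannot beat it
      if (bestI >= 0 && std::sqrt(best) <= (double)ring * h) break;
      if (!any && bestI >= 0) break;
    }
    if (bestI < 0) { // brute fallback (should not happen)
      for (int i = 0; i < nr; ++i) {
        double d2 = sq(qx - ref(i, 0)) + sq(qy - ref(i, 1)) + sq(qz - ref(i, 2));
        if (d2 < best) { best = d2; bestI = i; }
      }
    }
    idx[p] = bestI + 1;
    dist[p] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
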