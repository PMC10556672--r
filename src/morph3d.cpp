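// 3D morphology primitives: connected-component labelling, anisotropic
// squared Euclidean distance transform, and seeded watershed flooding.
// These operate on flat arrays with explicit dims so the same code serves
// 2D images (connectivity 4/8) and 3D stacks (connectivity 6/26).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

struct Off {
  int dx, dy, dz;
};

static std::vector<Off> neighbor_offsets(int ndim, int connectivity) {
  std::vector<Off> offs;
  if (ndim == 2) {
    bool diag = (connectivity == 8);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        if (!diag && std::abs(dx) + std::abs(dy) > 1) continue;
        offs.push_back({dx, dy, 0});
      }
  } else {
    bool diag = (connectivity == 26);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (!diag && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1) continue;
          offs.push_back({dx, dy, dz});
        }
  }
  return offs;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int ndim = dims.size();
  if (ndim != 2 && ndim != 3) stop("dims must have length 2 or 3");
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<Off> offs = neighbor_offsets(ndim, connectivity);

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        int xx = x + offs[k].dx, yy = y + offs[k].dy, zz = z + offs[k].dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Felzenszwalb & Huttenlocher 1D lower-envelope distance transform,
// with squared sample spacing w2 (anisotropic voxels).
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (physical units) from each foreground voxel to
// the nearest background voxel. Background (and the array border, implicitly
// not) is at distance 0; border is NOT treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int ndim = dims.size();
  if (ndim != 2 && ndim != 3) stop("dims must have length 2 or 3");
  if ((int)spacing.size() != ndim) stop("spacing must match dims");
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = 1e30;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx);
  d.resize(nx);
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, w2);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny);
  d.resize(ny);
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y)
        f[y] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, d, ny, w2);
      for (int y = 0; y < ny; ++y)
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
    }
  // pass along z
  if (ndim == 3 && nz > 1) {
    f.resize(nz);
    d.resize(nz);
    w2 = spacing[2] * spacing[2];
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z)
          f[z] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        dt1d(f, d, nz, w2);
        for (int z = 0; z < nz; ++z)
          out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
      }
  }
  out.attr("dim") = dims;
  return out;
}

struct QItem {
  double elev;
  unsigned long order;
  R_xlen_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.elev != b.elev) return a.elev < b.elev; // max-heap on elevation
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Meyer-style seeded flooding on an elevation map (descending order):
// regions grow outward from seeds, highest elevation first.
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector elev, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int ndim = dims.size();
  if (ndim != 2 && ndim != 3) stop("dims must have length 2 or 3");
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (elev.size() != n || seeds.size() != n || mask.size() != n)
    stop("array lengths do not match dims");
  std::vector<Off> offs = neighbor_offsets(ndim, connectivity);

  IntegerVector labels(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push({elev[i], order++, i, seeds[i]});
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    R_xlen_t v = it.idx;
    int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
    for (size_t k = 0; k < offs.size(); ++k) {
      int xx = x + offs[k].dx, yy = y + offs[k].dy, zz = z + offs[k].dz;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (mask[w] && labels[w] == 0) {
        labels[w] = labels[v];
        pq.push({elev[w], order++, w, labels[w]});
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
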