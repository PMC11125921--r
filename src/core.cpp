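#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Neighbourhood offsets for 6/18/26 connectivity in (z,y,x) voxel space.
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// [[Rcpp::export]]
IntegerVector cpp_connected_components(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  auto off = neighbour_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v % nz), y = (int)((v / nz) % ny), x = (int)(v / ((R_xlen_t)nz * ny));
      for (auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Large finite stand-in for "no source on this line"; final distances at
// or above sqrt(BIG/2) are reported as +Inf by the caller.
static const double DT_BIG = 1e20;

// 1D squared distance transform (lower envelope of parabolas), sample
// spacing w: d(p) = min_q f(q) + (w * (p - q))^2. In-place on f.
static void dt1d(std::vector<double> &f, double w) {
  int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> zb(n + 1), d(n);
  const double INF = std::numeric_limits<double>::infinity();
  double w2 = w * w;
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; if (k < 0) break; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = (k == 0) ? -INF : s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel
// of `mask`, under anisotropic spacing (z,y,x). Infinite if mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  out.attr("dim") = dims;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : DT_BIG;
  std::vector<double> line;
  // pass along z (first, fastest-varying dimension)
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) line[z] = out[base + z];
      dt1d(line, spacing[0]);
      for (int z = 0; z < nz; ++z) out[base + z] = line[z];
    }
  // pass along y
  line.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y)
        line[y] = out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y)
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = line[y];
    }
  // pass along x
  line.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x)
        line[x] = out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(line, spacing[2]);
      for (int x = 0; x < nx; ++x)
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = line[x];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= DT_BIG / 2.0) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

struct WsNode {
  double value;
  unsigned long order;
  R_xlen_t index;
  int label;
};
struct WsCompare {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.order > b.order;                          // FIFO tie-break
  }
};

// Seeded watershed on `priority` restricted to `mask`. Seeds are 0-based
// linear indices with labels 1..k. Flooding proceeds in ascending priority;
// ties broken by insertion (scan) order. Voxels of the mask not reachable
// from any seed stay 0 (the caller assigns them to the nearest seed).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector mask,
                            IntegerVector seed_index, IntegerVector seed_label,
                            int connectivity) {
  IntegerVector dims = mask.attr("dim");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  auto off = neighbour_offsets(connectivity);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> heap;
  unsigned long counter = 0;
  for (int s = 0; s < seed_index.size(); ++s) {
    R_xlen_t v = seed_index[s];
    if (v < 0 || v >= n || !mask[v])
      stop("watershed seed outside the mask");
    heap.push({priority[v], counter++, v, seed_label[s]});
  }
  while (!heap.empty()) {
    WsNode nd = heap.top(); heap.pop();
    R_xlen_t v = nd.index;
    if (lab[v] != 0) continue;
    lab[v] = nd.label;
    int z = (int)(v % nz), y = (int)((v / nz) % ny), x = (int)(v / ((R_xlen_t)nz * ny));
    for (auto &o : off) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (mask[w] && lab[w] == 0)
        heap.push({priority[w], counter++, w, nd.label});
    }
  }
  return lab;
}
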