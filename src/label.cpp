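#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Neighbour offsets for 6- or 26-connectivity on an (nx, ny, nz) grid.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Connected-component labelling of a binary mask. Labels are assigned in
// raster-scan order of each component's first voxel, so output is
// deterministic. Returns integer volume with 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  auto off = neighbour_offsets(connectivity);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t q = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Plateau-aware local maxima of `value` restricted to `mask` (26-connected).
// A plateau (connected set of equal values) is a maximum iff none of its
// voxels has a masked neighbour with a strictly greater value; each maximum
// plateau contributes one seed: its minimum linear voxel index.
// Returns 1-based linear indices of the seeds, sorted ascending.
// [[Rcpp::export]]
IntegerVector cpp_plateau_maxima(NumericVector value, LogicalVector mask,
                                 IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  auto off = neighbour_offsets(26);
  std::vector<int> plab(ntot, 0);
  std::vector<size_t> stack;
  std::vector<int> seeds;
  int next = 0;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || plab[s] != 0) continue;
    ++next;
    double v0 = value[s];
    bool is_max = true;
    size_t rep = s; // minimum linear index of the plateau
    plab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      if (cur < rep) rep = cur;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t q = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (!mask[q]) continue;
        if (value[q] > v0) is_max = false;
        else if (value[q] == v0 && plab[q] == 0) {
          plab[q] = next;
          stack.push_back(q);
        }
      }
    }
    if (is_max) seeds.push_back((int)rep + 1);
  }
  std::sort(seeds.begin(), seeds.end());
  return wrap(seeds);
}

struct WsNode {
  double height;   // flooding pops the highest value first
  uint64_t order;  // insertion counter; earlier insertions win ties
  size_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.height != b.height) return a.height < b.height; // max-heap
    return a.order > b.order;                             // FIFO on ties
  }
};

// Seeded watershed by priority flooding, descending `value` (here: the
// distance transform), 26-connected, restricted to `mask`. seeds are 1-based
// linear indices; returns a label volume, seed i -> label i.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector value, LogicalVector mask,
                            IntegerVector seeds, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  auto off = neighbour_offsets(26);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  uint64_t counter = 0;
  for (int i = 0; i < seeds.size(); ++i) {
    size_t s = (size_t)seeds[i] - 1;
    pq.push({value[s], counter++, s, i + 1});
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    if (lab[nd.idx] != 0) continue;
    lab[nd.idx] = nd.label;
    int x = nd.idx % nx, y = (nd.idx / nx) % ny, z = nd.idx / ((size_t)nx * ny);
    for (auto &o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      size_t q = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
      if (mask[q] && lab[q] == 0) pq.push({value[q], counter++, q, nd.label});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
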