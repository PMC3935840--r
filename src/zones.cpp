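#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label maximal connected components of equal value on a 3-D integer grid.
// `levels` is the flattened (column-major) grid; 0 marks background.
// `offsets` is a K x 3 matrix of neighbour displacements in (x, y, z).
// Returns labels in 1..n_zones (0 for background), assigned in scan order.
// [[Rcpp::export(name = ".labelZonesCpp")]]
IntegerVector label_zones_cpp(IntegerVector levels, IntegerVector dims,
                              IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (levels.size() != n) stop("levels length does not match dims");
  IntegerVector labels(n, 0);
  const int K = offsets.nrow();
  std::vector<int> stack;
  stack.reserve(1024);
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (levels[start] == 0 || labels[start] != 0) continue;
    const int lev = levels[start];
    ++next_label;
    labels[start] = next_label;
    stack.push_back((int)start);
    while (!stack.empty()) {
      const int idx = stack.back();
      stack.pop_back();
      const int x = idx % nx;
      const int y = (idx / nx) % ny;
      const int z = idx / (nx * ny);
      for (int k = 0; k < K; ++k) {
        const int xx = x + offsets(k, 0);
        const int yy = y + offsets(k, 1);
        const int zz = z + offsets(k, 2);
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int nidx = xx + nx * (yy + ny * zz);
        if (labels[nidx] == 0 && levels[nidx] == lev) {
          labels[nidx] = next_label;
          stack.push_back(nidx);
        }
      }
    }
  }
  labels.attr("n_zones") = next_label;
  return labels;
}
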