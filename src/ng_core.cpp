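#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a binary 3D mask by iterative flood
// fill. Returns an integer array of the same shape: 0 = background,
// 1..n_components = component id (ordered by first voxel encountered).
// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    stack.push_back(s);
    labels[s] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && labels[w] == 0) {
              labels[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}

// Greedy non-maximum suppression: candidates must be pre-sorted by
// descending score; positions is an n x 3 matrix. Returns (1-based) indices
// of accepted candidates, at most top_n, no two closer than radius.
// [[Rcpp::export(name = ".nms_select")]]
IntegerVector nms_select(NumericMatrix positions, double radius, int top_n) {
  const double r2 = radius * radius;
  std::vector<int> kept;
  const int n = positions.nrow();
  for (int i = 0; i < n && (int)kept.size() < top_n; ++i) {
    bool ok = true;
    for (size_t j = 0; j < kept.size(); ++j) {
      int kj = kept[j];
      double dx = positions(i, 0) - positions(kj, 0);
      double dy = positions(i, 1) - positions(kj, 1);
      double dz = positions(i, 2) - positions(kj, 2);
      if (dx * dx + dy * dy + dz * dz < r2) { ok = false; break; }
    }
    if (ok) kept.push_back(i);
  }
  IntegerVector out(kept.size());
  for (size_t j = 0; j < kept.size(); ++j) out[j] = kept[j] + 1;
  return out;
}
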