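#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary voxel grid by flood fill.
// `dim` has length 2 or 3; `connectivity` is 6, 18 or 26 in 3-D
// (4 or 8 in 2-D, mapped by the R wrapper onto the 3-D codes).
// Labels are assigned in first-encounter (column-major) order, which makes
// the labeling deterministic for a given input.
// [[Rcpp::export(name = ".label_cc_cpp")]]
IntegerVector label_cc_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0];
  const int ny = dim.size() > 1 ? dim[1] : 1;
  const int nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int nn = (int)ox.size();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int cur = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++cur;
    labels[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p / sz);
      int rem = (int)(p - (R_xlen_t)z * sz);
      int y = rem / nx;
      int x = rem - y * nx;
      for (int k = 0; k < nn; ++k) {
        int qx = x + ox[k], qy = y + oy[k], qz = z + oz[k];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz) continue;
        R_xlen_t q = qx * sx + (R_xlen_t)qy * sy + (R_xlen_t)qz * sz;
        if (mask[q] && labels[q] == 0) {
          labels[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("n_components") = cur;
  return labels;
}
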