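#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labeling on a logical volume.
//
// `fg` is a logical vector in R array order for a (nz, ny, nx) array
// (z fastest, then y, then x). Returns an integer vector of the same
// length: 0 for background, components labeled 1..n in order of first
// (linear-index) encounter. `connectivity` is 6, 18 or 26.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector fg, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (fg.size() != n) stop("fg length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets for the requested order
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        int s = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!fg[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (fg[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
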