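#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D connected-component labeling of a binary mask by breadth-first search.
// mask: logical/integer vector in column-major order for an array of
// dimension (nz, ny, nx); connectivity one of 6, 18, 26.
// Returns integer labels (0 = background), contiguous from 1 in the order
// the first voxel of each component is reached by a raster scan.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets in (dz, dy, dx)
  std::vector<int> dz_, dy_, dx_;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int nzero = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nzero == 0) continue;
        if (connectivity == 6 && nzero > 1) continue;
        if (connectivity == 18 && nzero > 2) continue;
        dz_.push_back(dz); dy_.push_back(dy); dx_.push_back(dx);
      }
  const int nn = (int)dz_.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t v = queue[head++];
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz_[k], yy = y + dy_[k], xx = x + dx_[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
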