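#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected components of a 3D integer label volume. Two voxels belong to the
// same component iff they carry the same nonzero label and are adjacent under
// the requested connectivity (6 = faces, 18 = faces+edges, 26 = full cube).
// Component ids are assigned in scan order of their seed voxel, so the result
// is deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector labels, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (labels.size() != n) stop("labels length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int noff = (int)dxs.size();

  IntegerVector comp(n, 0);
  std::vector<R_xlen_t> stack;
  int next_id = 0;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (labels[seed] == 0 || comp[seed] != 0) continue;
    const int lab = labels[seed];
    ++next_id;
    comp[seed] = next_id;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cz = (int)(cur / nxy);
      const int rem = (int)(cur - (R_xlen_t)cz * nxy);
      const int cy = rem / nx;
      const int cx = rem - cy * nx;
      for (int o = 0; o < noff; ++o) {
        const int x = cx + dxs[o], y = cy + dys[o], z = cz + dzs[o];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const R_xlen_t idx = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        if (comp[idx] == 0 && labels[idx] == lab) {
          comp[idx] = next_id;
          stack.push_back(idx);
        }
      }
    }
  }
  return comp;
}
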