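#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Arrays arrive as R vectors with dim (nz, ny, nx), column-major, so the
// linear index of voxel (z, y, x) (0-based) is z + nz * (y + ny * x).
// "Raster order" for label assignment iterates z slowest, x fastest.

static inline int vidx(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

struct Offsets {
  std::vector<int> dz, dy, dx;
};

static Offsets neighbor_offsets(int connectivity) {
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        o.dz.push_back(dz); o.dy.push_back(dy); o.dx.push_back(dx);
      }
  return o;
}

// Label connected components of a logical mask under 6- or 26-connectivity.
// Components are numbered 1..K in order of their first voxel encountered in
// (z, y, x) raster order (z slowest, x fastest).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int V = nz * ny * nx;
  if (mask.size() != V) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  Offsets off = neighbor_offsets(connectivity);
  const int noff = (int)off.dz.size();

  IntegerVector labels(V, 0);
  std::vector<int> stack;
  int next = 0;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(z, y, x, nz, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cz = cur % nz;
          int rest = cur / nz;
          int cy = rest % ny;
          int cx = rest / ny;
          for (int k = 0; k < noff; ++k) {
            int zz = cz + off.dz[k], yy = cy + off.dy[k], xx = cx + off.dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = vidx(zz, yy, xx, nz, ny);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  labels.attr("n") = next;
  return labels;
}

// Seeded growth phase of the split algorithm. `seeds` holds seed indices
// 1..n on seed voxels and 0 elsewhere; growth is confined to `inregion`.
// The working intensity steps down through `steps` (strictly decreasing,
// starting at the seed threshold, ending at the region minimum); each step is
// one simultaneous 1-voxel dilation of all seeds into unclaimed region voxels
// with intensity >= the working intensity. A voxel reachable from several
// seeds in the same step goes to the seed whose claiming neighbor has the
// highest intensity, ties to the lowest seed index. After the last step,
// dilation repeats at the minimum intensity until no voxel changes.
// [[Rcpp::export(name = ".grow_seeds")]]
IntegerVector grow_seeds(IntegerVector seeds, LogicalVector inregion,
                         NumericVector intens, IntegerVector dims,
                         int connectivity, NumericVector steps) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int V = nz * ny * nx;
  if (seeds.size() != V || inregion.size() != V || intens.size() != V)
    stop("array length mismatch");
  Offsets off = neighbor_offsets(connectivity);
  const int noff = (int)off.dz.size();

  IntegerVector claimed = clone(seeds);

  // Unclaimed region voxels, visited linearly; compact list for speed.
  std::vector<int> pending;
  pending.reserve(V / 4);
  for (int i = 0; i < V; ++i)
    if (inregion[i] && claimed[i] == 0) pending.push_back(i);

  std::vector<int> claim_v, claim_s;

  const int nsteps = steps.size();
  int step = 0;
  while (true) {
    double w = steps[std::min(step, nsteps - 1)];
    claim_v.clear(); claim_s.clear();
    for (size_t p = 0; p < pending.size(); ++p) {
      int i = pending[p];
      if (intens[i] < w) continue;
      int cz = i % nz;
      int rest = i / nz;
      int cy = rest % ny;
      int cx = rest / ny;
      double best_int = -1.0;
      int best_seed = 0;
      for (int k = 0; k < noff; ++k) {
        int zz = cz + off.dz[k], yy = cy + off.dy[k], xx = cx + off.dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = vidx(zz, yy, xx, nz, ny);
        int s = claimed[j];
        if (s == 0) continue;
        double nb = intens[j];
        if (nb > best_int || (nb == best_int && s < best_seed)) {
          best_int = nb;
          best_seed = s;
        }
      }
      if (best_seed > 0) { claim_v.push_back(i); claim_s.push_back(best_seed); }
    }
    for (size_t k = 0; k < claim_v.size(); ++k) claimed[claim_v[k]] = claim_s[k];
    if (!claim_v.empty()) {
      size_t keep = 0;
      for (size_t p = 0; p < pending.size(); ++p)
        if (claimed[pending[p]] == 0) pending[keep++] = pending[p];
      pending.resize(keep);
    }
    if (step < nsteps - 1) {
      ++step;
    } else {
      // converged at the minimum intensity: stop when a pass adds nothing
      if (claim_v.empty()) break;
    }
  }
  return claimed;
}
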