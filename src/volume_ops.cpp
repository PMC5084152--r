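// Low-level 3-D volume operations used by the enhancement and segmentation
// stages. All volumes are R arrays with dim = (nz, ny, nx), column-major, so
// linear index = iz + nz * (iy + ny * ix).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lindex(int iz, int iy, int ix, int nz, int ny) {
  return iz + nz * (iy + ny * ix);
}

// 26-connected component labelling of a logical mask.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int next_label = 0;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(start);
    labels[start] = next_label;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int iz = cur % nz;
      int rest = cur / nz;
      int iy = rest % ny;
      int ix = rest / ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z = iz + dz, y = iy + dy, x = ix + dx;
            if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
              continue;
            int idx = lindex(z, y, x, nz, ny);
            if (mask[idx] && labels[idx] == 0) {
              labels[idx] = next_label;
              stack.push_back(idx);
            }
          }
    }
  }
  return labels;
}

// Local maxima of `vol` above `threshold`, with anisotropic exclusion
// radius (rxy voxels in x/y, rz in z). A voxel is a candidate when it is
// >= all neighbours in its exclusion neighbourhood; among candidates closer
// than the radius, the brighter one wins (ties: smaller linear index).
// Returns an n x 3 matrix of 1-based (z, y, x) voxel coordinates.
// [[Rcpp::export(name = ".local_maxima_3d")]]
IntegerMatrix local_maxima_3d(NumericVector vol, IntegerVector dims,
                              int rxy, int rz, double threshold) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> cand;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        int idx = lindex(iz, iy, ix, nz, ny);
        double v = vol[idx];
        if (v < threshold) continue;
        bool is_max = true;
        for (int dz = -rz; dz <= rz && is_max; ++dz)
          for (int dy = -rxy; dy <= rxy && is_max; ++dy)
            for (int dx = -rxy; dx <= rxy && is_max; ++dx) {
              if (!dz && !dy && !dx) continue;
              int z = iz + dz, y = iy + dy, x = ix + dx;
              if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
                continue;
              int jdx = lindex(z, y, x, nz, ny);
              if (vol[jdx] > v || (vol[jdx] == v && jdx < idx)) is_max = false;
            }
        if (is_max) cand.push_back(idx);
      }
  IntegerMatrix out(cand.size(), 3);
  for (size_t k = 0; k < cand.size(); ++k) {
    int idx = cand[k];
    out(k, 0) = idx % nz + 1;
    out(k, 1) = (idx / nz) % ny + 1;
    out(k, 2) = idx / (nz * ny) + 1;
  }
  return out;
}

struct WsNode {
  double relief;
  long order;
  int idx;
};
struct WsCompare {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.relief != b.relief) return a.relief > b.relief; // min-heap on relief
    return a.order > b.order;                             // FIFO tie-break
  }
};

// Marker-controlled watershed by priority flooding, restricted to `mask`.
// `markers` holds positive seed labels (0 elsewhere); voxels outside the
// mask stay 0. Every flooded voxel inherits the label of the seed whose
// basin reaches it first (lowest relief first), so the output label count
// equals the marker label count exactly.
// [[Rcpp::export(name = ".watershed_3d")]]
IntegerVector watershed_3d(NumericVector relief, LogicalVector mask,
                           IntegerVector markers, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> pq;
  long counter = 0;
  for (int i = 0; i < n; ++i) {
    if (markers[i] > 0) {
      if (!mask[i]) stop("marker outside mask");
      labels[i] = markers[i];
      pq.push({relief[i], counter++, i});
    }
  }
  while (!pq.empty()) {
    WsNode node = pq.top(); pq.pop();
    int cur = node.idx;
    int iz = cur % nz;
    int rest = cur / nz;
    int iy = rest % ny;
    int ix = rest / ny;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z = iz + dz, y = iy + dy, x = ix + dx;
          if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
            continue;
          int idx = lindex(z, y, x, nz, ny);
          if (!mask[idx] || labels[idx] != 0) continue;
          labels[idx] = labels[cur];
          double lvl = relief[idx] > node.relief ? relief[idx] : node.relief;
          pq.push({lvl, counter++, idx});
        }
  }
  return labels;
}

// In-place box filter (sum over window +-r, clipped at the borders) along
// one dimension of a (nz, ny, nx) column-major volume, via running sums.
static void box_filter_dim(std::vector<double> &a, int nz, int ny, int nx,
                           int r, int dim) {
  if (r < 1) return;
  int n = dim == 0 ? nz : (dim == 1 ? ny : nx);
  int stride = dim == 0 ? 1 : (dim == 1 ? nz : nz * ny);
  int n_lines = (nz * ny * nx) / n;
  std::vector<double> line(n);
  for (int l = 0; l < n_lines; ++l) {
    // base index of this line
    int base;
    if (dim == 0) base = l * nz;
    else if (dim == 1) { int z = l % nz, x = l / nz; base = z + nz * ny * x; }
    else base = l;
    for (int i = 0; i < n; ++i) line[i] = a[base + i * stride];
    double run = 0.0;
    for (int i = 0; i <= r && i < n; ++i) run += line[i];
    for (int i = 0; i < n; ++i) {
      a[base + i * stride] = run;
      int add = i + r + 1, rem = i - r;
      if (add < n) run += line[add];
      if (rem >= 0) run -= line[rem];
    }
  }
}

// Feature-preserving non-local means. Patch similarity is measured on the
// intensity patch concatenated with the particle-probability patch (the PP
// channel scaled by `beta` after bringing intensities to unit scale), so
// particle voxels preferentially average with particle voxels.
// h is the filtering strength on the normalised intensity scale.
// Implemented per search offset with box-filtered squared-difference
// volumes (integral-image trick), so the cost is independent of patch size.
// [[Rcpp::export(name = ".fp_nlm_3d")]]
NumericVector fp_nlm_3d(NumericVector vol, NumericVector pp,
                        IntegerVector dims, int patch_rxy, int patch_rz,
                        int search_rxy, int search_rz, double h, double beta) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  NumericVector out(n);
  out.attr("dim") = dims;
  double vmin = R_PosInf, vmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (vol[i] < vmin) vmin = vol[i];
    if (vol[i] > vmax) vmax = vol[i];
  }
  double range = vmax - vmin;
  if (range <= 0) { // constant volume: nothing to do
    for (int i = 0; i < n; ++i) out[i] = vol[i];
    return out;
  }
  const double inv_range2 = 1.0 / (range * range);
  const double inv_h2 = 1.0 / (h * h);
  const bool use_pp = pp.size() == n && beta > 0;
  const double beta2 = beta * beta;

  std::vector<double> wsum(n, 0.0), acc(n, 0.0);
  std::vector<double> d2(n), cnt(n);

  for (int sz = -search_rz; sz <= search_rz; ++sz)
    for (int sy = -search_rxy; sy <= search_rxy; ++sy)
      for (int sx = -search_rxy; sx <= search_rxy; ++sx) {
        // squared-difference volume for this offset (invalid -> 0 with
        // count 0, so border patches use their in-bounds pairs only)
        for (int ix = 0; ix < nx; ++ix) {
          int bx = ix + sx;
          bool okx = bx >= 0 && bx < nx;
          for (int iy = 0; iy < ny; ++iy) {
            int by = iy + sy;
            bool oky = okx && by >= 0 && by < ny;
            int col_a = nz * (iy + ny * ix);
            int col_b = nz * (by + ny * bx);
            for (int iz = 0; iz < nz; ++iz) {
              int bz = iz + sz;
              int ai = col_a + iz;
              if (oky && bz >= 0 && bz < nz) {
                int bi = col_b + bz;
                double di = vol[ai] - vol[bi];
                double v = di * di * inv_range2;
                if (use_pp) {
                  double dp = pp[ai] - pp[bi];
                  v += beta2 * dp * dp;
                }
                d2[ai] = v;
                cnt[ai] = 1.0;
              } else {
                d2[ai] = 0.0;
                cnt[ai] = 0.0;
              }
            }
          }
        }
        // box-filter distances and valid-pair counts over the patch window
        box_filter_dim(d2, nz, ny, nx, patch_rz, 0);
        box_filter_dim(d2, nz, ny, nx, patch_rxy, 1);
        box_filter_dim(d2, nz, ny, nx, patch_rxy, 2);
        box_filter_dim(cnt, nz, ny, nx, patch_rz, 0);
        box_filter_dim(cnt, nz, ny, nx, patch_rxy, 1);
        box_filter_dim(cnt, nz, ny, nx, patch_rxy, 2);
        // accumulate weights; the centre voxel of the neighbour patch must
        // itself be in bounds (cnt > 0 there implies it is, since the
        // centre pair contributes whenever valid)
        for (int ix = 0; ix < nx; ++ix) {
          int bx = ix + sx;
          if (bx < 0 || bx >= nx) continue;
          for (int iy = 0; iy < ny; ++iy) {
            int by = iy + sy;
            if (by < 0 || by >= ny) continue;
            int col_a = nz * (iy + ny * ix);
            int col_b = nz * (by + ny * bx);
            for (int iz = 0; iz < nz; ++iz) {
              int bz = iz + sz;
              if (bz < 0 || bz >= nz) continue;
              int ai = col_a + iz;
              double c = cnt[ai];
              if (c <= 0) continue;
              double w = std::exp(-(d2[ai] / c) * inv_h2);
              wsum[ai] += w;
              acc[ai] += w * vol[col_b + bz];
            }
          }
        }
      }
  for (int i = 0; i < n; ++i) out[i] = acc[i] / wsum[i];
  return out;
}
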