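// Low-level 3D grid primitives shared by the segmentation stack:
// separable convolution, 6-connected component labeling, 26-connected
// local maxima, and seeded watershed by priority flooding.
// Arrays are column-major with dim = (Z, Y, X); linear index
// i = z + Z*(y + Y*x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // mirror boundary without repeating the edge sample twice past the end
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  if (x.size() != n) stop("data length does not match dim");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int klen = kernel.size();
  if (klen % 2 != 1) stop("kernel length must be odd");
  const int kh = klen / 2;

  const R_xlen_t stride[3] = {1, (R_xlen_t)Z, (R_xlen_t)Z * Y};
  const int len[3] = {Z, Y, X};
  const int L = len[axis];
  const R_xlen_t s = stride[axis];

  NumericVector out(n);
  out.attr("dim") = dim;

  // iterate over all lines along `axis`
  int a1 = (axis == 0) ? 1 : 0;
  int a2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(L);
  for (int j2 = 0; j2 < len[a2]; ++j2) {
    for (int j1 = 0; j1 < len[a1]; ++j1) {
      R_xlen_t base = (R_xlen_t)j1 * stride[a1] + (R_xlen_t)j2 * stride[a2];
      for (int i = 0; i < L; ++i) line[i] = x[base + (R_xlen_t)i * s];
      for (int i = 0; i < L; ++i) {
        double acc = 0.0;
        for (int k = -kh; k <= kh; ++k)
          acc += kernel[k + kh] * line[reflect_idx(i + k, L)];
        out[base + (R_xlen_t)i * s] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  const R_xlen_t dz = 1, dy = Z, dx = (R_xlen_t)Z * Y;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v / dx);
      int rem = (int)(v % dx);
      int y = rem / Z;
      int z = rem % Z;
      R_xlen_t nb[6];
      int nn = 0;
      if (z > 0) nb[nn++] = v - dz;
      if (z < Z - 1) nb[nn++] = v + dz;
      if (y > 0) nb[nn++] = v - dy;
      if (y < Y - 1) nb[nn++] = v + dy;
      if (x > 0) nb[nn++] = v - dx;
      if (x < X - 1) nb[nn++] = v + dx;
      for (int k = 0; k < nn; ++k) {
        R_xlen_t w = nb[k];
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector x, IntegerVector dim) {
  // 26-connected strict maxima; plateaus resolved by keeping only the
  // lowest linear index among equal-valued neighbors
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  if (x.size() != n) stop("data length does not match dim");
  LogicalVector out(n, false);
  out.attr("dim") = dim;
  for (int xx = 0; xx < X; ++xx) {
    for (int yy = 0; yy < Y; ++yy) {
      for (int zz = 0; zz < Z; ++zz) {
        R_xlen_t i = zz + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx);
        double v = x[i];
        bool is_max = true;
        for (int ddx = -1; ddx <= 1 && is_max; ++ddx) {
          int nx = xx + ddx;
          if (nx < 0 || nx >= X) continue;
          for (int ddy = -1; ddy <= 1 && is_max; ++ddy) {
            int ny = yy + ddy;
            if (ny < 0 || ny >= Y) continue;
            for (int ddz = -1; ddz <= 1; ++ddz) {
              int nz = zz + ddz;
              if (nz < 0 || nz >= Z) continue;
              if (ddx == 0 && ddy == 0 && ddz == 0) continue;
              R_xlen_t j = nz + (R_xlen_t)Z * (ny + (R_xlen_t)Y * nx);
              double w = x[j];
              if (w > v || (w == v && j < i)) { is_max = false; break; }
            }
          }
        }
        out[i] = is_max;
      }
    }
  }
  return out;
}

struct WsEntry {
  double prio;
  std::uint64_t order;
  R_xlen_t idx;
  int label;
};
struct WsCompare {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO among ties
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector marker,
                              IntegerVector dim) {
  // marker: > 0 seed label, 0 floodable, < 0 blocked (never assigned).
  // Floods ascending priority from the seeds; 6-connectivity.
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  if (priority.size() != n || marker.size() != n)
    stop("length does not match dim");
  IntegerVector lab = clone(marker);
  lab.attr("dim") = dim;
  const R_xlen_t dz = 1, dy = Z, dx = (R_xlen_t)Z * Y;

  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  std::uint64_t order = 0;

  auto push_neighbors = [&](R_xlen_t v, int label) {
    int x = (int)(v / dx);
    int rem = (int)(v % dx);
    int y = rem / Z;
    int z = rem % Z;
    R_xlen_t nb[6];
    int nn = 0;
    if (z > 0) nb[nn++] = v - dz;
    if (z < Z - 1) nb[nn++] = v + dz;
    if (y > 0) nb[nn++] = v - dy;
    if (y < Y - 1) nb[nn++] = v + dy;
    if (x > 0) nb[nn++] = v - dx;
    if (x < X - 1) nb[nn++] = v + dx;
    for (int k = 0; k < nn; ++k) {
      R_xlen_t w = nb[k];
      if (lab[w] == 0)
        pq.push(WsEntry{priority[w], order++, w, label});
    }
  };

  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i] > 0) push_neighbors(i, lab[i]);

  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.label;
    push_neighbors(e.idx, e.label);
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i] < 0) lab[i] = 0;
  return lab;
}
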