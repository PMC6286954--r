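#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grids are R matrices (column-major); pixel (r, c) lives at r + c * nr.
// "Raster-scan order" throughout means row-major reading order: row by row,
// left to right, matching how the label/tie-break contracts are stated.

static inline int idx_of(int r, int c, int nr) { return r + c * nr; }

// 8-neighbour offsets in the fixed contract order N, E, S, W, NE, SE, SW, NW.
static const int DR8[8] = { -1, 0, 1, 0, -1, 1, 1, -1 };
static const int DC8[8] = { 0, 1, 0, -1, 1, 1, -1, -1 };
// 4-neighbour subset (N, E, S, W).
static const int DR4[4] = { -1, 0, 1, 0 };
static const int DC4[4] = { 0, 1, 0, -1 };

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int nnb = connectivity;
  const int* dr = (connectivity == 8) ? DR8 : DR4;
  const int* dc = (connectivity == 8) ? DC8 : DC4;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  // Discover components in raster-scan order so labels are assigned by the
  // position of each component's first pixel.
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(idx_of(r, c, nr));
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int cr = i % nr, cc2 = i / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + dr[k], c2 = cc2 + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(idx_of(r2, c2, nr));
          }
        }
      }
    }
  }
  return lab;
}

// Exact city-block (L1) distance to the nearest TRUE cell, two-pass chamfer.
// Cells at distance 0 are the set itself; empty set gives large sentinel.
static std::vector<int> l1_dist(const LogicalMatrix& mask, bool to_true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int BIG = nr + nc + 2;
  std::vector<int> d((size_t)nr * nc, BIG);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if ((bool)mask(r, c) == to_true) d[idx_of(r, c, nr)] = 0;
  // forward: top-left to bottom-right, 4-neighbour predecessors
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = idx_of(r, c, nr);
      if (r > 0 && d[idx_of(r - 1, c, nr)] + 1 < d[i]) d[i] = d[idx_of(r - 1, c, nr)] + 1;
      if (c > 0 && d[idx_of(r, c - 1, nr)] + 1 < d[i]) d[i] = d[idx_of(r, c - 1, nr)] + 1;
    }
  }
  // backward
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      int i = idx_of(r, c, nr);
      if (r < nr - 1 && d[idx_of(r + 1, c, nr)] + 1 < d[i]) d[i] = d[idx_of(r + 1, c, nr)] + 1;
      if (c < nc - 1 && d[idx_of(r, c + 1, nr)] + 1 < d[i]) d[i] = d[idx_of(r, c + 1, nr)] + 1;
    }
  }
  return d;
}

// [[Rcpp::export]]
LogicalMatrix dilate_l1_cpp(LogicalMatrix mask, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> d = l1_dist(mask, true);
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = d[idx_of(r, c, nr)] <= radius;
  return out;
}

// [[Rcpp::export]]
LogicalMatrix erode_l1_cpp(LogicalMatrix mask, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> d = l1_dist(mask, false); // distance to background
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = d[idx_of(r, c, nr)] > radius;
  return out;
}

// Morphological closing with the L1-ball (diamond) structuring element:
// dilation followed by erosion, both exact via distance transforms.
// [[Rcpp::export]]
LogicalMatrix closing_l1_cpp(LogicalMatrix mask, int radius) {
  LogicalMatrix dil = dilate_l1_cpp(mask, radius);
  return erode_l1_cpp(dil, radius);
}

struct Cand {
  double h;
  long long ord;
  int label;
  int idx;
};
struct CandLess {
  // priority_queue pops the "largest": we want highest height first,
  // and among equal heights the earliest-pushed candidate (FIFO).
  bool operator()(const Cand& a, const Cand& b) const {
    if (a.h != b.h) return a.h < b.h;
    return a.ord > b.ord;
  }
};

// Marker-controlled watershed on the negated height surface: flooding starts
// from marker pixels, always advancing into the highest unclaimed foliage
// pixel next (crowns are basins of -height). Fully deterministic: FIFO among
// equal heights, neighbours pushed in N,E,S,W,NE,SE,SW,NW order, marker
// pixels seeded in raster-scan order. Marker labels are never overwritten.
// [[Rcpp::export]]
IntegerMatrix watershed_flood_cpp(NumericMatrix height, IntegerMatrix markers,
                                  LogicalMatrix foliage) {
  const int nr = height.nrow(), nc = height.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      foliage.nrow() != nr || foliage.ncol() != nc)
    stop("height, markers and foliage must share the same grid");
  IntegerMatrix out(nr, nc);
  std::priority_queue<Cand, std::vector<Cand>, CandLess> pq;
  long long ord = 0;
  // seed: copy marker labels, then push their unlabeled foliage neighbours
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = markers(r, c);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int lab = markers(r, c);
      if (lab <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR8[k], c2 = c + DC8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!foliage(r2, c2) || out(r2, c2) != 0) continue;
        double h = height(r2, c2);
        if (NumericMatrix::is_na(h)) continue;
        pq.push(Cand{ h, ord++, lab, idx_of(r2, c2, nr) });
      }
    }
  }
  while (!pq.empty()) {
    Cand cd = pq.top(); pq.pop();
    int r = cd.idx % nr, c = cd.idx / nr;
    if (out(r, c) != 0) continue; // claimed earlier at equal/higher priority
    out(r, c) = cd.label;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!foliage(r2, c2) || out(r2, c2) != 0) continue;
      double h = height(r2, c2);
      if (NumericMatrix::is_na(h)) continue;
      pq.push(Cand{ h, ord++, cd.label, idx_of(r2, c2, nr) });
    }
  }
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 4 sigma and renormalized
// at the borders (no padding bias). Used by the orchard simulator to emulate
// the smoothing that photogrammetric noise filtering imprints on real DSMs.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix x, double sigma) {
  const int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int half = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * half + 1);
  for (int i = -half; i <= half; ++i)
    k[i + half] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0, w = 0;
      int lo = std::max(0, r - half), hi = std::min(nr - 1, r + half);
      for (int r2 = lo; r2 <= hi; ++r2) {
        double kv = k[r2 - r + half];
        s += kv * x(r2, c); w += kv;
      }
      tmp(r, c) = s / w;
    }
  }
  // along columns (horizontal)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0, w = 0;
      int lo = std::max(0, c - half), hi = std::min(nc - 1, c + half);
      for (int c2 = lo; c2 <= hi; ++c2) {
        double kv = k[c2 - c + half];
        s += kv * tmp(r, c2); w += kv;
      }
      out(r, c) = s / w;
    }
  }
  return out;
}
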