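#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Pixel-level kernels shared by the image modules. Matrices are R column-major;
// (i, j) below are 0-based row/col indices.

// Disk-shaped median filter with replicated borders. Radius in pixels; a pixel
// (di, dj) belongs to the window iff di^2 + dj^2 <= r^2.
// [[Rcpp::export]]
NumericMatrix cpp_median_disk(NumericMatrix img, int radius) {
  if (radius < 1) stop("radius must be >= 1");
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> di, dj;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { di.push_back(a); dj.push_back(b); }
  int w = di.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int k = 0; k < w; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        buf[k] = img(ii, jj);
      }
      int mid = w / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (w % 2 == 0) {
        // even window cannot occur for a disk (centre + symmetric pairs), kept for safety
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

static inline int px(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) != 0 ? 1 : 0;
}

// Guo-Hall two-subiteration thinning to convergence. Preserves 8-connectivity
// topology; idempotent once converged. Input/output: 0/1 matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_thin_guo_hall(IntegerMatrix binary) {
  int nr = binary.nrow(), nc = binary.ncol();
  IntegerMatrix im(clone(binary));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      im(i, j) = im(i, j) != 0 ? 1 : 0;
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!im(i, j)) continue;
          int p2 = px(im, i - 1, j),     p3 = px(im, i - 1, j + 1);
          int p4 = px(im, i,     j + 1), p5 = px(im, i + 1, j + 1);
          int p6 = px(im, i + 1, j),     p7 = px(im, i + 1, j - 1);
          int p8 = px(im, i,     j - 1), p9 = px(im, i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        im(kill[k].first, kill[k].second) = 0;
    }
  }
  return im;
}

// 8-connected component labeling by BFS flood fill. Labels 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix binary) {
  int nr = binary.nrow(), nc = binary.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (binary(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int a = -1; a <= 1; ++a) {
          for (int b = -1; b <= 1; ++b) {
            if (a == 0 && b == 0) continue;
            int ii = p.first + a, jj = p.second + b;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (binary(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Count of 8-neighbours that are foreground, for every pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(IntegerMatrix binary) {
  int nr = binary.nrow(), nc = binary.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int s = 0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          if (a == 0 && b == 0) continue;
          s += px(binary, i + a, j + b);
        }
      out(i, j) = s;
    }
  return out;
}
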