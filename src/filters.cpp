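#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Local mean suppression filter. Window sums use zero padding outside the
// image, and the divisor is the full window size (2*n0+1)^2 regardless of
// clipping. Summation order is column-major within the window, identical to
// R's sum() over an extracted submatrix, so results are bit-reproducible
// against a plain double-loop reference.
// [[Rcpp::export]]
NumericMatrix lmsf_cpp(NumericMatrix I, double t0, int n0) {
  int nr = I.nrow(), nc = I.ncol();
  NumericMatrix out(nr, nc);
  const double win = (2.0 * n0 + 1.0) * (2.0 * n0 + 1.0);
  const double* p = &I[0];
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(0, j - n0), j1 = std::min(nc - 1, j + n0);
    for (int i = 0; i < nr; ++i) {
      double v = p[i + j * nr];
      if (v == 0.0) { out(i, j) = 0.0; continue; }   // zero maps to zero
      int i0 = std::max(0, i - n0), i1 = std::min(nr - 1, i + n0);
      double s = 0.0;
      for (int jj = j0; jj <= j1; ++jj) {
        const double* col = p + (size_t)jj * nr;
        for (int ii = i0; ii <= i1; ++ii)
          s += col[ii];
      }
      double m = s / win;
      out(i, j) = (m <= 0.0 || v / m < t0) ? 0.0 : v;
    }
  }
  return out;
}

// Per-pixel two-class Otsu threshold over a disk neighbourhood, on a
// 256-bin histogram of [0,1] intensities. Returns a 0/1 matrix: pixel is
// foreground iff its bin strictly exceeds the local Otsu bin. Neighbourhoods
// with fewer than two occupied bins yield background.
// [[Rcpp::export]]
IntegerMatrix local_otsu_cpp(NumericMatrix I, int r0) {
  int nr = I.nrow(), nc = I.ncol();
  IntegerMatrix out(nr, nc);
  // precompute disk offsets
  std::vector<int> di, dj;
  for (int a = -r0; a <= r0; ++a)
    for (int b = -r0; b <= r0; ++b)
      if (a * a + b * b <= r0 * r0) { di.push_back(a); dj.push_back(b); }
  int noff = (int)di.size();
  // precompute bins
  IntegerMatrix bin(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int b = (int)(I(i, j) * 256.0);
      bin(i, j) = b > 255 ? 255 : (b < 0 ? 0 : b);
    }
  std::vector<double> hist(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      std::fill(hist.begin(), hist.end(), 0.0);
      int n = 0, bmin = 256, bmax = -1;
      for (int k = 0; k < noff; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int b = bin(ii, jj);
        hist[b] += 1.0; ++n;
        if (b < bmin) bmin = b;
        if (b > bmax) bmax = b;
      }
      if (bmax <= bmin) { out(i, j) = 0; continue; }  // zero-variance window
      double total = (double)n, sumAll = 0.0;
      for (int b = bmin; b <= bmax; ++b) sumAll += b * hist[b];
      double wB = 0.0, sumB = 0.0, best = -1.0;
      int tbest = bmin;
      for (int t = bmin; t < bmax; ++t) {
        wB += hist[t]; sumB += t * hist[t];
        if (wB <= 0.0) continue;
        double wF = total - wB;
        if (wF <= 0.0) break;
        double mB = sumB / wB, mF = (sumAll - sumB) / wF;
        double v = wB * wF * (mB - mF) * (mB - mF);
        if (v > best) { best = v; tbest = t; }
      }
      out(i, j) = bin(i, j) > tbest ? 1 : 0;
    }
  }
  return out;
}
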