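#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect an out-of-range 0-based index into [0, n) (symmetric padding,
// edge pixel included: d c b a | a b c d | d c b a).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Median over a digital disk neighbourhood (dy^2 + dx^2 <= radius^2),
// pixel included, reflect padding. Disk offset counts are always odd, so
// the median is the middle order statistic.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(NumericMatrix x, double radius) {
  int n = x.nrow(), m = x.ncol();
  int k = (int)std::floor(radius);
  std::vector<int> dys, dxs;
  for (int dy = -k; dy <= k; ++dy)
    for (int dx = -k; dx <= k; ++dx)
      if (dy * dy + dx * dx <= radius * radius + 1e-9) {
        dys.push_back(dy); dxs.push_back(dx);
      }
  int w = (int)dys.size();
  NumericMatrix out(n, m);
  std::vector<double> buf(w);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < w; ++t) {
        int r = reflect_idx(i + dys[t], n);
        int c = reflect_idx(j + dxs[t], m);
        buf[t] = x(r, c);
      }
      std::nth_element(buf.begin(), buf.begin() + w / 2, buf.end());
      out(i, j) = buf[w / 2];
    }
  }
  return out;
}

// Minimum over a digital disk neighbourhood (grayscale erosion), reflect
// padding.
// [[Rcpp::export]]
NumericMatrix cpp_disk_min(NumericMatrix x, double radius) {
  int n = x.nrow(), m = x.ncol();
  int k = (int)std::floor(radius);
  std::vector<int> dys, dxs;
  for (int dy = -k; dy <= k; ++dy)
    for (int dx = -k; dx <= k; ++dx)
      if (dy * dy + dx * dx <= radius * radius + 1e-9) {
        dys.push_back(dy); dxs.push_back(dx);
      }
  int w = (int)dys.size();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double mn = R_PosInf;
      for (int t = 0; t < w; ++t) {
        int r = reflect_idx(i + dys[t], n);
        int c = reflect_idx(j + dxs[t], m);
        if (x(r, c) < mn) mn = x(r, c);
      }
      out(i, j) = mn;
    }
  }
  return out;
}
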