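#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Intensities of the raster cells traversed from round(p0) to round(p1)
// under 8-connected Bresenham. Coordinates are 0-based (x = column, y = row).
// Inclusive of both endpoints: an axis-aligned segment spanning n cells
// yields exactly n samples.
// [[Rcpp::export]]
NumericVector sample_bresenham_cpp(const NumericMatrix& img,
                                   double x0d, double y0d,
                                   double x1d, double y1d) {
  const int nr = img.nrow(), nc = img.ncol();
  int x0 = (int)std::lround(x0d), y0 = (int)std::lround(y0d);
  int x1 = (int)std::lround(x1d), y1 = (int)std::lround(y1d);
  const int dx = std::abs(x1 - x0), dy = std::abs(y1 - y0);
  const int sx = x0 < x1 ? 1 : -1, sy = y0 < y1 ? 1 : -1;
  const int n = std::max(dx, dy) + 1;
  NumericVector out(n);
  int err = dx - dy, x = x0, y = y0;
  for (int i = 0; i < n; ++i) {
    if (x < 0 || x >= nc || y < 0 || y >= nr)
      stop("sample_bresenham_cpp: cell (%d, %d) outside image", x, y);
    out[i] = img(y, x);
    const int e2 = 2 * err;
    if (e2 > -dy) { err -= dy; x += sx; }
    if (e2 <  dx) { err += dx; y += sy; }
  }
  return out;
}

// Separable Gaussian blur with reflected edges; kernel radius ceil(3*sigma).
// Used on 24-megapixel rasters where an FFT-based convolution is wasteful.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  // both passes sweep whole columns so access stays column-major contiguous
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* src = img.begin();
  double* t = tmp.begin();
  // horizontal pass: out column x accumulates neighbouring columns
  for (int x = 0; x < nc; ++x) {
    double* col = t + (R_xlen_t)x * nr;
    for (int i = -r; i <= r; ++i) {
      int xx = x + i;
      if (xx < 0) xx = -xx - 1;
      if (xx >= nc) xx = 2 * nc - xx - 1;
      const double w = k[i + r];
      const double* in = src + (R_xlen_t)xx * nr;
      if (i == -r) for (int y = 0; y < nr; ++y) col[y] = w * in[y];
      else         for (int y = 0; y < nr; ++y) col[y] += w * in[y];
    }
  }
  // vertical pass: within each column
  double* o = out.begin();
  for (int x = 0; x < nc; ++x) {
    const double* col = t + (R_xlen_t)x * nr;
    double* oc = o + (R_xlen_t)x * nr;
    for (int y = 0; y < nr; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = -yy - 1;
        if (yy >= nr) yy = 2 * nr - yy - 1;
        acc += k[i + r] * col[yy];
      }
      oc[y] = acc;
    }
  }
  return out;
}

// 256-bin histogram of an 8-bit raster (values assumed in [0, 255]).
// [[Rcpp::export]]
IntegerVector hist256_cpp(const NumericMatrix& img) {
  IntegerVector h(256);
  const R_xlen_t n = (R_xlen_t)img.nrow() * img.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    int v = (int)std::lround(img[i]);
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    h[v]++;
  }
  return h;
}
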