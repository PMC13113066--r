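#include <Rcpp.h>
using namespace Rcpp;

// One-pass echotexture feature extraction for 8-bit integer-valued images:
// mean, population variance, histogram deciles q10..q90, central-region
// mean (rows r0..r1, cols c0..c1, 1-based inclusive), gradient energy and
// row-profile maximum. Returns NULL when a pixel is outside [0, 255] or
// non-integer so the caller can fall back to the generic R path.
// [[Rcpp::export]]
SEXP cpp_features(const NumericMatrix& px, int r0, int r1, int c0, int c1) {
  const int h = px.nrow(), w = px.ncol();
  const double n = (double)h * w;
  std::vector<double> hist(256, 0.0);
  double sum = 0.0, sumsq = 0.0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const double v = px(r, c);
      if (v < 0 || v > 255 || v != (double)(int)v) return R_NilValue;
      hist[(int)v] += 1.0;
      sum += v;
      sumsq += v * v;
    }
  }
  const double mean = sum / n;
  const double var = sumsq / n - mean * mean;

  NumericVector out(14);
  out[0] = mean;
  out[1] = var;
  // deciles as order statistics: smallest value with cdf >= ceil(n * q)
  double cdf = 0.0;
  int qi = 0;
  double targets[9];
  for (int k = 0; k < 9; ++k) {
    double t = std::ceil(n * (k + 1) / 10.0);
    targets[k] = t < 1.0 ? 1.0 : t;
  }
  for (int v = 0; v < 256 && qi < 9; ++v) {
    cdf += hist[v];
    while (qi < 9 && cdf >= targets[qi]) out[2 + qi++] = v;
  }

  double csum = 0.0;
  for (int c = c0 - 1; c < c1; ++c)
    for (int r = r0 - 1; r < r1; ++r) csum += px(r, c);
  out[11] = csum / ((double)(r1 - r0 + 1) * (c1 - c0 + 1));

  double grad = 0.0;
  for (int c = 0; c < w - 1; ++c)
    for (int r = 0; r < h; ++r) {
      const double d = px(r, c + 1) - px(r, c);
      grad += d * d;
    }
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h - 1; ++r) {
      const double d = px(r + 1, c) - px(r, c);
      grad += d * d;
    }
  out[12] = grad / ((double)h * (w - 1) + (double)(h - 1) * w);

  double rowmax = R_NegInf;
  for (int r = 0; r < h; ++r) {
    double rs = 0.0;
    for (int c = 0; c < w; ++c) rs += px(r, c);
    rs /= w;
    if (rs > rowmax) rowmax = rs;
  }
  out[13] = rowmax;
  return out;
}
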