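#include <Rcpp.h>
using namespace Rcpp;

// Inverse-map warp with bilinear interpolation and edge-clamped sampling.
// `inv` is the 3x3 matrix taking output pixel coordinates (x = column,
// y = row, 1-based) to input coordinates; projective division is applied,
// so affine and full homography transforms share this path.
// [[Rcpp::export]]
NumericMatrix cpp_warp(const NumericMatrix& px, const NumericMatrix& inv) {
  const int h = px.nrow(), w = px.ncol();
  NumericMatrix out(h, w);
  const double a11 = inv(0, 0), a12 = inv(0, 1), a13 = inv(0, 2);
  const double a21 = inv(1, 0), a22 = inv(1, 1), a23 = inv(1, 2);
  const double a31 = inv(2, 0), a32 = inv(2, 1), a33 = inv(2, 2);
  for (int c = 0; c < w; ++c) {
    const double x = c + 1.0;
    for (int r = 0; r < h; ++r) {
      const double y = r + 1.0;
      const double d = a31 * x + a32 * y + a33;
      double xi = (a11 * x + a12 * y + a13) / d;
      double yi = (a21 * x + a22 * y + a23) / d;
      if (xi < 1.0) xi = 1.0; else if (xi > w) xi = w;
      if (yi < 1.0) yi = 1.0; else if (yi > h) yi = h;
      int x0 = (int)xi, y0 = (int)yi;
      if (x0 > w - 1) x0 = w - 1;
      if (y0 > h - 1) y0 = h - 1;
      const double fx = xi - x0, fy = yi - y0;
      const int x1 = (x0 < w) ? x0 : w - 1;      // x0 is 1-based
      const double v00 = px(y0 - 1, x0 - 1);
      const double v01 = px(y0 - 1, x1);
      const double v10 = px(y0, x0 - 1);
      const double v11 = px(y0, x1);
      out(r, c) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return out;
}
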