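#include <Rcpp.h>
using namespace Rcpp;

// Inverse-mapped resampling of a single-channel image under a similarity
// transform.  The forward transform maps moving-image coordinates into
// fixed-image coordinates:
//
//   x_f = c + t + s * R(theta) * (x_m - c)
//
// with c the transform centre, t = (tx, ty) and R a CCW rotation.  The
// output grid is the fixed frame (h_out x w_out, pixel centres at 0-based
// integer coordinates, x = column, y = row); each output pixel samples the
// moving image at the inverse-mapped location.  Out-of-domain samples are
// NaN so callers can choose a fill value or restrict statistics to the
// overlap region.
//
// [[Rcpp::export]]
NumericMatrix cpp_resample_similarity(const NumericMatrix& img,
                                      int h_out, int w_out,
                                      double theta, double scale,
                                      double tx, double ty,
                                      double cx, double cy,
                                      bool bilinear) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h_out, w_out);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double inv_s = 1.0 / scale;
  // inverse: x_m = c + (1/s) * R(-theta) * (x_f - c - t)
  for (int j = 0; j < w_out; ++j) {
    const double xf = static_cast<double>(j) - cx - tx;
    for (int i = 0; i < h_out; ++i) {
      const double yf = static_cast<double>(i) - cy - ty;
      const double xm = cx + inv_s * ( ct * xf + st * yf);
      const double ym = cy + inv_s * (-st * xf + ct * yf);
      double v = NA_REAL;
      if (bilinear) {
        if (xm >= 0.0 && xm <= w - 1.0 && ym >= 0.0 && ym <= h - 1.0) {
          int x0 = static_cast<int>(std::floor(xm));
          int y0 = static_cast<int>(std::floor(ym));
          if (x0 == w - 1) x0--;
          if (y0 == h - 1) y0--;
          const double fx = xm - x0, fy = ym - y0;
          v = (1 - fy) * ((1 - fx) * img(y0, x0)     + fx * img(y0, x0 + 1)) +
              fy       * ((1 - fx) * img(y0 + 1, x0) + fx * img(y0 + 1, x0 + 1));
        }
      } else {
        const int xn = static_cast<int>(std::lround(xm));
        const int yn = static_cast<int>(std::lround(ym));
        if (xn >= 0 && xn < w && yn >= 0 && yn < h) v = img(yn, xn);
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Joint histogram of two equal-length vectors over a bins x bins grid.
// Values are binned over [amin, amax] and [bmin, bmax]; pairs with a
// non-finite member (NaN from out-of-overlap resampling) are skipped.
//
// [[Rcpp::export]]
IntegerMatrix cpp_joint_hist(const NumericVector& a, const NumericVector& b,
                             int bins,
                             double amin, double amax,
                             double bmin, double bmax) {
  IntegerMatrix h(bins, bins);
  const double ra = (amax > amin) ? bins / (amax - amin) : 0.0;
  const double rb = (bmax > bmin) ? bins / (bmax - bmin) : 0.0;
  const R_xlen_t n = a.size();
  for (R_xlen_t k = 0; k < n; ++k) {
    const double av = a[k], bv = b[k];
    if (!R_finite(av) || !R_finite(bv)) continue;
    int ia = (ra > 0.0) ? static_cast<int>((av - amin) * ra) : 0;
    int ib = (rb > 0.0) ? static_cast<int>((bv - bmin) * rb) : 0;
    if (ia < 0) ia = 0; else if (ia >= bins) ia = bins - 1;
    if (ib < 0) ib = 0; else if (ib >= bins) ib = bins - 1;
    h(ia, ib)++;
  }
  return h;
}
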