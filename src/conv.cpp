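#include <Rcpp.h>
using namespace Rcpp;

// Separable 2-D convolution, "valid" mode: only window positions fully
// inside the image contribute. The SSIM window is a symmetric Gaussian, so
// convolution and correlation coincide. Output is
// (nrow - w + 1) x (ncol - w + 1).
// [[Rcpp::export]]
NumericMatrix conv2_sep_valid(const NumericMatrix& x, const NumericVector& kern) {
  const int w = kern.size();
  const int nr = x.nrow(), nc = x.ncol();
  const int orow = nr - w + 1, ocol = nc - w + 1;
  if (orow < 1 || ocol < 1)
    stop("image (%d x %d) smaller than the %d-pixel window", nr, nc, w);

  // vertical pass: tmp(i, j) = sum_m kern[m] * x(i + m, j)
  NumericMatrix tmp(orow, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < orow; ++i) {
      double acc = 0.0;
      for (int m = 0; m < w; ++m) acc += kern[m] * x(i + m, j);
      tmp(i, j) = acc;
    }
  }
  // horizontal pass: out(i, j) = sum_m kern[m] * tmp(i, j + m)
  NumericMatrix out(orow, ocol);
  for (int j = 0; j < ocol; ++j) {
    for (int i = 0; i < orow; ++i) {
      double acc = 0.0;
      for (int m = 0; m < w; ++m) acc += kern[m] * tmp(i, j + m);
      out(i, j) = acc;
    }
  }
  return out;
}
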