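// Separable Gaussian filtering and bilinear resampling.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// symmetric (edge-inclusive) mirror index into [0, n)
inline int mirror(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

arma::vec gauss_kernel(double sigma, int radius) {
  arma::vec k(2 * radius + 1);
  for (int i = -radius; i <= radius; ++i)
    k(i + radius) = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  return k / arma::accu(k);
}

}  // namespace

// Separable convolution with a normalized sampled Gaussian, mirror boundary.
// radius < 0 selects the default truncation at ceil(4*sigma).
// [[Rcpp::export(name = ".gauss_filter")]]
NumericMatrix gauss_filter(NumericMatrix img, double sigma, int radius = -1) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0.0) return clone(img);
  if (radius < 0) radius = (int)std::ceil(4.0 * sigma);
  arma::vec k = gauss_kernel(sigma, radius);

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // filter along rows (y direction)
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double s = 0.0;
      for (int t = -radius; t <= radius; ++t)
        s += k(t + radius) * img(mirror(y + t, nr), x);
      tmp(y, x) = s;
    }
  // filter along columns (x direction)
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double s = 0.0;
      for (int t = -radius; t <= radius; ++t)
        s += k(t + radius) * tmp(y, mirror(x + t, nc));
      out(y, x) = s;
    }
  return out;
}

// Bilinear upsampling by an integer factor with pixel-centre alignment:
// output pixel i maps to input coordinate (i + 0.5)/factor - 0.5.
// [[Rcpp::export(name = ".bilinear_upsample")]]
NumericMatrix bilinear_upsample(NumericMatrix img, int factor) {
  const int nr = img.nrow(), nc = img.ncol();
  const int NR = nr * factor, NC = nc * factor;
  NumericMatrix out(NR, NC);
  for (int X = 0; X < NC; ++X) {
    double sx = (X + 0.5) / factor - 0.5;
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    int xa = std::min(std::max(x0, 0), nc - 1);
    int xb = std::min(std::max(x0 + 1, 0), nc - 1);
    for (int Y = 0; Y < NR; ++Y) {
      double sy = (Y + 0.5) / factor - 0.5;
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      int ya = std::min(std::max(y0, 0), nr - 1);
      int yb = std::min(std::max(y0 + 1, 0), nr - 1);
      out(Y, X) = (1 - fx) * ((1 - fy) * img(ya, xa) + fy * img(yb, xa)) +
                  fx * ((1 - fy) * img(ya, xb) + fy * img(yb, xb));
    }
  }
  return out;
}
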