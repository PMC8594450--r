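// Clustered lumpy background rendering.
//
// A CLB image is a sum of many elongated exponential blobs
//   l(r, R_theta) = exp(-alpha * ||r||^beta / L(R_theta r)),
// where L(u) is the radius of the (Lx, Ly) ellipse along the direction of u.
// With the default beta = 0.5 the blob tails decay so slowly that every blob
// contributes over the whole field, so per-pixel evaluation of thousands of
// blobs dominates simulation cost.  The renderer therefore evaluates each
// blob exactly on a fine grid near its centre and on a coarse lattice far
// away, blending the two with a smooth radial crossfade; the coarse far-field
// accumulator is bilinearly upsampled once per image.  An exact (all fine)
// path is kept for validation.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// blob value at offset (dx, dy) from its centre, orientation theta
inline double blob_value(double dx, double dy, double ct, double st,
                         double alpha, double beta, double Lx, double Ly) {
  const double u = ct * dx + st * dy;
  const double v = -st * dx + ct * dy;
  const double r2 = u * u + v * v;
  if (r2 < 1e-24) return 1.0;
  // alpha * r^beta / L(phi) = (alpha/(Lx*Ly)) * sqrt(Ly^2 u^2 + Lx^2 v^2) * r^(beta-1)
  const double q = std::sqrt(Ly * Ly * u * u + Lx * Lx * v * v);
  double rpow;
  if (beta == 0.5) {
    rpow = 1.0 / std::sqrt(std::sqrt(r2));  // r^(-1/2)
  } else {
    rpow = std::pow(r2, 0.5 * (beta - 1.0));
  }
  const double expo = (alpha / (Lx * Ly)) * q * rpow;
  return std::exp(-expo);
}

// single-precision variant for bulk accumulation (the texture is a sum of
// thousands of O(1) terms, so float rounding is far below sampling noise)
inline float blob_value_f(float dx, float dy, float ct, float st,
                          float a0, float beta, float Lx2, float Ly2) {
  const float u = ct * dx + st * dy;
  const float v = -st * dx + ct * dy;
  const float r2 = u * u + v * v;
  if (r2 < 1e-12f) return 1.0f;
  const float q = std::sqrt(Ly2 * u * u + Lx2 * v * v);
  float rpow;
  if (beta == 0.5f) {
    rpow = 1.0f / std::sqrt(std::sqrt(r2));
  } else {
    rpow = std::pow(r2, 0.5f * (beta - 1.0f));
  }
  return std::exp(-a0 * q * rpow);
}

}  // namespace

// [[Rcpp::export(name = ".clb_render")]]
NumericMatrix clb_render(int n, NumericVector bx, NumericVector by,
                         NumericVector theta, double alpha, double beta,
                         double Lx, double Ly, double amplitude,
                         bool exact = false) {
  const int nb = bx.size();
  NumericMatrix out(n, n);  // row = y, col = x
  if (nb == 0) return out;

  if (exact) {
    for (int b = 0; b < nb; ++b) {
      const double ct = std::cos(theta[b]), st = std::sin(theta[b]);
      for (int x = 0; x < n; ++x) {
        const double dx = x - bx[b];
        for (int y = 0; y < n; ++y) {
          out(y, x) += blob_value(dx, y - by[b], ct, st, alpha, beta, Lx, Ly);
        }
      }
    }
    for (int i = 0; i < n * n; ++i) out[i] *= amplitude;
    return out;
  }

  // hybrid near/far evaluation
  const float r0 = 9.0f, r1 = 15.0f;        // crossfade radii (pixels)
  const float r1sq = r1 * r1;
  const float inv_cross = 1.0f / (r1 - r0);
  const int h = 4;                          // coarse lattice spacing
  const int nc = (n - 1 + h - 1) / h + 1;   // covers [0, (nc-1)*h] >= n-1
  arma::fmat coarse(nc, nc, arma::fill::zeros);
  const float a0 = (float)(alpha / (Lx * Ly));
  const float Lx2 = (float)(Lx * Lx), Ly2 = (float)(Ly * Ly);
  const float betaf = (float)beta;

  for (int b = 0; b < nb; ++b) {
    const float cx = (float)bx[b], cy = (float)by[b];
    const float ct = std::cos((float)theta[b]);
    const float st = std::sin((float)theta[b]);

    // near field, fine grid, weight w(r)
    int x0 = std::max(0, (int)std::ceil(cx - r1));
    int x1 = std::min(n - 1, (int)std::floor(cx + r1));
    for (int x = x0; x <= x1; ++x) {
      const float dx = x - cx;
      const float span2 = r1sq - dx * dx;
      if (span2 <= 0) continue;
      const float span = std::sqrt(span2);
      int y0 = std::max(0, (int)std::ceil(cy - span));
      int y1 = std::min(n - 1, (int)std::floor(cy + span));
      for (int y = y0; y <= y1; ++y) {
        const float dy = y - cy;
        const float rr = dx * dx + dy * dy;
        if (rr >= r1sq) continue;
        const float r = std::sqrt(rr);
        const float w = (r <= r0) ? 1.0f : (r1 - r) * inv_cross;
        out(y, x) += w * blob_value_f(dx, dy, ct, st, a0, betaf, Lx2, Ly2);
      }
    }

    // far field on the coarse lattice, weight 1 - w(r)
    for (int kx = 0; kx < nc; ++kx) {
      const float dx = kx * h - cx;
      for (int ky = 0; ky < nc; ++ky) {
        const float dy = ky * h - cy;
        const float r = std::sqrt(dx * dx + dy * dy);
        if (r <= r0) continue;
        const float w2 = (r >= r1) ? 1.0f : (r - r0) * inv_cross;
        coarse(ky, kx) +=
            w2 * blob_value_f(dx, dy, ct, st, a0, betaf, Lx2, Ly2);
      }
    }
  }

  // bilinear upsample of the coarse accumulator onto the fine grid
  for (int x = 0; x < n; ++x) {
    const double gx = (double)x / h;
    int i0 = (int)gx;
    if (i0 >= nc - 1) i0 = nc - 2;
    const double fx = gx - i0;
    for (int y = 0; y < n; ++y) {
      const double gy = (double)y / h;
      int j0 = (int)gy;
      if (j0 >= nc - 1) j0 = nc - 2;
      const double fy = gy - j0;
      const double val =
          (1 - fx) * ((1 - fy) * coarse(j0, i0) + fy * coarse(j0 + 1, i0)) +
          fx * ((1 - fy) * coarse(j0, i0 + 1) + fy * coarse(j0 + 1, i0 + 1));
      out(y, x) += val;
    }
  }

  for (int i = 0; i < n * n; ++i) out[i] *= amplitude;
  return out;
}

// [[Rcpp::export(name = ".clb_blob_value")]]
double clb_blob_value(double dx, double dy, double theta, double alpha,
                      double beta, double Lx, double Ly) {
  return blob_value(dx, dy, std::cos(theta), std::sin(theta), alpha, beta, Lx,
                    Ly);
}
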