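#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian blur with edge replication, kernel radius 3*sigma.
// [[Rcpp::export]]
NumericMatrix blur_sep_cpp(const NumericMatrix& m, double sigma) {
  int nr = m.nrow(), nc = m.ncol();
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    w[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += w[k + r];
  }
  for (double& v : w) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass
  for (int j = 0; j < nc; ++j) {
    const double* col = &m(0, j);
    double* t = &tmp(0, j);
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += w[k + r] * col[ii];
      }
      t[i] = acc;
    }
  }
  // horizontal pass: accumulate whole columns for contiguous access
  for (int j = 0; j < nc; ++j) {
    double* o = &out(0, j);
    for (int k = -r; k <= r; ++k) {
      int jj = j + k;
      if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
      const double* t = &tmp(0, jj);
      double wk = w[k + r];
      for (int i = 0; i < nr; ++i) o[i] += wk * t[i];
    }
  }
  return out;
}

// Add a soft-edged capsule (full amplitude within halfwidth of the axis
// segment, Gaussian falloff outside) to the canvas, in place.
// [[Rcpp::export]]
NumericMatrix add_capsule_cpp(NumericMatrix canvas, double x0, double y0,
                              double x1, double y1, double halfwidth,
                              double amp, double edge_sigma) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  double reach = halfwidth + 3.5 * edge_sigma;
  int rlo = std::max(0, (int)std::floor(std::min(y0, y1) - reach) - 1);
  int rhi = std::min(nr - 1, (int)std::ceil(std::max(y0, y1) + reach) + 1);
  int clo = std::max(0, (int)std::floor(std::min(x0, x1) - reach) - 1);
  int chi = std::min(nc - 1, (int)std::ceil(std::max(x0, x1) + reach) + 1);
  double dx = x1 - x0, dy = y1 - y0;
  double L2 = dx * dx + dy * dy;
  double inv2s2 = 1.0 / (2.0 * edge_sigma * edge_sigma);
  for (int j = clo; j <= chi; ++j) {
    double px = j + 1.0;            // 1-based pixel coordinates
    for (int i = rlo; i <= rhi; ++i) {
      double py = i + 1.0;
      double t = L2 > 0 ? ((px - x0) * dx + (py - y0) * dy) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double ex = px - (x0 + t * dx), ey = py - (y0 + t * dy);
      double d = std::sqrt(ex * ex + ey * ey);
      if (d <= halfwidth) canvas(i, j) += amp;
      else if (d < reach) {
        double e = d - halfwidth;
        canvas(i, j) += amp * std::exp(-e * e * inv2s2);
      }
    }
  }
  return canvas;
}

// Add an isotropic Gaussian blob to the canvas, in place.
// [[Rcpp::export]]
NumericMatrix add_gaussian_cpp(NumericMatrix canvas, double x, double y,
                               double amp, double sigma) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  double reach = 4.5 * sigma;
  int rlo = std::max(0, (int)std::floor(y - reach) - 1);
  int rhi = std::min(nr - 1, (int)std::ceil(y + reach) + 1);
  int clo = std::max(0, (int)std::floor(x - reach) - 1);
  int chi = std::min(nc - 1, (int)std::ceil(x + reach) + 1);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int j = clo; j <= chi; ++j) {
    double ddx = (j + 1.0) - x;
    for (int i = rlo; i <= rhi; ++i) {
      double ddy = (i + 1.0) - y;
      canvas(i, j) += amp * std::exp(-(ddx * ddx + ddy * ddy) * inv2s2);
    }
  }
  return canvas;
}

// Add N(0, sd) noise (R's RNG stream), clip to the 16-bit range and round.
// [[Rcpp::export]]
NumericMatrix finish_channel_cpp(const NumericMatrix& m, double noise_sd) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  RNGScope scope;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = m(i, j);
      if (noise_sd > 0) v += R::rnorm(0.0, noise_sd);
      if (v < 0) v = 0; else if (v > 65535) v = 65535;
      out(i, j) = std::round(v);
    }
  }
  return out;
}
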