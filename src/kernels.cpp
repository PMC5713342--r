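// Fused elementwise kernels for the neural-network training loop.
// Matrix products go through BLAS; these kernels avoid the temporary
// allocations R would make for the optimizer and batch-normalization
// elementwise passes. In-place arguments are owned by the training loop
// (deep-copied once when training starts).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Adam step, in place: p -= lr * mhat / (sqrt(vhat) + eps)
// [[Rcpp::export(rng = false)]]
void adam_step_(NumericVector p, NumericVector m, NumericVector v,
                NumericVector g, double lr, double b1, double b2,
                double eps, int t, double wd) {
  const R_xlen_t n = p.size();
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + wd * p[i];
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// column-standardize into a fresh matrix: (x - center) / scale
// [[Rcpp::export(rng = false)]]
NumericMatrix scale_columns_(NumericMatrix x, NumericVector center,
                             NumericVector scale) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double c = center[j], s = scale[j];
    const double *src = &x(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = (src[i] - c) / s;
  }
  return out;
}

// plain gradient step, in place
// [[Rcpp::export(rng = false)]]
void sgd_step_(NumericVector p, NumericVector g, double lr, double wd) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) p[i] -= lr * (g[i] + wd * p[i]);
}

// inverted-dropout masked copy (input layer); uses R's RNG
// [[Rcpp::export]]
NumericMatrix dropout_copy_(NumericMatrix x, double keep) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double scale = 1.0 / keep;
  for (int j = 0; j < nc; ++j) {
    const double *src = &x(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < nr; ++i) {
      dst[i] = unif_rand() < keep ? src[i] * scale : 0.0;
    }
  }
  return out;
}

// add a row vector to every row of a column-major matrix, in place
// [[Rcpp::export(rng = false)]]
void add_row_(NumericMatrix z, NumericVector b) {
  const int nr = z.nrow(), nc = z.ncol();
  for (int j = 0; j < nc; ++j) {
    double bj = b[j];
    double *col = &z(0, j);
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
}

// batch-norm training forward, in place: z -> xhat; returns per-column
// batch mean and 1/sqrt(var + eps)
// [[Rcpp::export(rng = false)]]
List bn_normalize_(NumericMatrix z, double eps) {
  const int nr = z.nrow(), nc = z.ncol();
  NumericVector mu(nc), inv_std(nc), var(nc);
  for (int j = 0; j < nc; ++j) {
    double *col = &z(0, j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < nr; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    const double m = s / nr;
    double v = s2 / nr - m * m;
    if (v < 0.0) v = 0.0;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[j] = m; var[j] = v; inv_std[j] = is;
    for (int i = 0; i < nr; ++i) col[i] = (col[i] - m) * is;
  }
  return List::create(_["mu"] = mu, _["var"] = var,
                      _["inv_std"] = inv_std);
}

// inference-mode batch norm + scale/shift, in place:
// z -> gamma * (z - mean) * inv_std + beta
// [[Rcpp::export(rng = false)]]
void bn_apply_(NumericMatrix z, NumericVector mean, NumericVector inv_std,
               NumericVector gamma, NumericVector beta) {
  const int nr = z.nrow(), nc = z.ncol();
  for (int j = 0; j < nc; ++j) {
    const double m = mean[j], is = inv_std[j], g = gamma[j], bt = beta[j];
    double *col = &z(0, j);
    for (int i = 0; i < nr; ++i) col[i] = g * (col[i] - m) * is + bt;
  }
}

// h = gamma * xhat + beta as a new matrix (xhat kept for backward)
// [[Rcpp::export(rng = false)]]
NumericMatrix scale_shift_(NumericMatrix xhat, NumericVector gamma,
                           NumericVector beta) {
  const int nr = xhat.nrow(), nc = xhat.ncol();
  NumericMatrix h(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double g = gamma[j], bt = beta[j];
    const double *src = &xhat(0, j);
    double *dst = &h(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = g * src[i] + bt;
  }
  return h;
}

// rectifier + inverted dropout, in place; returns the factor matrix F
// with a_out = h * F and d a_out / d h = F. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix relu_dropout_(NumericMatrix h, double keep) {
  const int nr = h.nrow(), nc = h.ncol();
  NumericMatrix f(nr, nc);
  const bool drop = keep < 1.0;
  const double scale = drop ? 1.0 / keep : 1.0;
  for (int j = 0; j < nc; ++j) {
    double *hc = &h(0, j);
    double *fc = &f(0, j);
    for (int i = 0; i < nr; ++i) {
      double fij = hc[i] > 0.0 ? scale : 0.0;
      if (drop && fij != 0.0 && unif_rand() >= keep) fij = 0.0;
      fc[i] = fij;
      hc[i] *= fij;
    }
  }
  return f;
}

// batch-norm backward: given dh (gradient at the scale/shift output),
// xhat and inv_std from the forward pass, produce the gradient at the
// pre-normalization input plus dgamma/dbeta.
// [[Rcpp::export(rng = false)]]
List bn_backward_(NumericMatrix dh, NumericMatrix xhat,
                  NumericVector gamma, NumericVector inv_std) {
  const int nr = dh.nrow(), nc = dh.ncol();
  NumericMatrix dz(nr, nc);
  NumericVector dgamma(nc), dbeta(nc);
  for (int j = 0; j < nc; ++j) {
    const double *dhc = &dh(0, j);
    const double *xc = &xhat(0, j);
    double *dzc = &dz(0, j);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < nr; ++i) {
      sg += dhc[i] * xc[i];
      sb += dhc[i];
    }
    dgamma[j] = sg; dbeta[j] = sb;
    const double g = gamma[j], is = inv_std[j];
    const double mean_dxhat = g * sb / nr;
    const double mean_dxhat_xhat = g * sg / nr;
    for (int i = 0; i < nr; ++i) {
      dzc[i] = (g * dhc[i] - mean_dxhat - xc[i] * mean_dxhat_xhat) * is;
    }
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
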