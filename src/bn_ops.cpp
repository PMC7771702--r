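// Batch-norm, ReLU and channel-bias kernels for (H, W, C, N) arrays.
// Per-channel statistics are taken over H, W and N jointly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, const arma::vec& gamma,
                const arma::vec& beta, const arma::vec& rmean,
                const arma::vec& rvar, bool training,
                double momentum, double eps) {
  IntegerVector d = dims4(x);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  const std::size_t cstep = HW, istep = (std::size_t)HW * C;
  arma::vec mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + n * istep + c * cstep;
        for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double m = s / ((double)HW * N);
      mu[c] = m;
      var[c] = s2 / ((double)HW * N) - m * m;
    }
  } else {
    mu = rmean; var = rvar;
  }
  arma::vec invstd = 1.0 / arma::sqrt(var + eps);
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = d; xhat.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + n * istep + c * cstep;
      double* ph = xhat.begin() + n * istep + c * cstep;
      double* py = y.begin() + n * istep + c * cstep;
      for (int i = 0; i < HW; ++i) {
        ph[i] = (p[i] - m) * is;
        py[i] = ph[i] * g + b;
      }
    }
  }
  List out = List::create(_["y"] = y, _["xhat"] = xhat,
                          _["invstd"] = NumericVector(invstd.begin(),
                                                      invstd.end()));
  if (training) {
    out["rmean"] = NumericVector::create();
    arma::vec nm = (1 - momentum) * rmean + momentum * mu;
    arma::vec nv = (1 - momentum) * rvar + momentum * var;
    out["rmean"] = NumericVector(nm.begin(), nm.end());
    out["rvar"] = NumericVector(nv.begin(), nv.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat,
                const arma::vec& gamma, const arma::vec& invstd) {
  IntegerVector d = dims4(dy);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  const std::size_t cstep = HW, istep = (std::size_t)HW * C;
  const double m = (double)HW * N;
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + n * istep + c * cstep;
      const double* ph = xhat.begin() + n * istep + c * cstep;
      for (int i = 0; i < HW; ++i) { sg += pdy[i] * ph[i]; sb += pdy[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], is = invstd[c];
    const double mean_dxh = g * sb / m, coef = g * sg / m;
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + n * istep + c * cstep;
      const double* ph = xhat.begin() + n * istep + c * cstep;
      double* pdx = dx.begin() + n * istep + c * cstep;
      for (int i = 0; i < HW; ++i)
        pdx[i] = is * (g * pdy[i] - mean_dxh - ph[i] * coef);
    }
  }
  return List::create(_["dx"] = dx,
                      _["dgamma"] = NumericVector(dgamma.begin(), dgamma.end()),
                      _["dbeta"] = NumericVector(dbeta.begin(), dbeta.end()));
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y) if (v < 0) v = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  return dx;
}

// y += bias per channel (dim 3 of 4).
// [[Rcpp::export]]
NumericVector cpp_add_channel_bias(NumericVector x, const arma::vec& b) {
  IntegerVector d = dims4(x);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y = clone(x);
  const std::size_t cstep = HW, istep = (std::size_t)HW * C;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double* p = y.begin() + n * istep + c * cstep;
      for (int i = 0; i < HW; ++i) p[i] += b[c];
    }
  return y;
}

// Per-channel sums of a 4-d array (bias gradients).
// [[Rcpp::export]]
NumericVector cpp_channel_sums(NumericVector x) {
  IntegerVector d = dims4(x);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  const std::size_t cstep = HW, istep = (std::size_t)HW * C;
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + n * istep + c * cstep;
      for (int i = 0; i < HW; ++i) s += p[i];
    }
    out[c] = s;
  }
  return out;
}
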