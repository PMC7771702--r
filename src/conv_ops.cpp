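// im2col-based 2-D convolution primitives used by the heatmap FCN and the
// bounding-box regressor.  Tensors are R arrays in (H, W, C, N) layout
// (column-major, so each image is a contiguous H*W*C block and each
// (oH, oW, C) output slice maps directly onto an (oH*oW) x C matrix).
// Weights are (kh*kw*Cin) x Cout matrices with kernel-element index
// k = dh + kh*(dw + kw*ci), matching column-major flattening of an
// (kh, kw, Cin, Cout) array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int oH, int oW, arma::mat& col) {
  for (int ci = 0; ci < C; ++ci) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int k = dh + kh * (dw + kw * ci);
        double* dst = col.colptr(k);
        for (int ow = 0; ow < oW; ++ow) {
          const int iw = ow * stride + dw - pad;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < oH; ++oh) dst[oh + oH * ow] = 0.0;
            continue;
          }
          const double* src = x + H * (iw + (std::size_t)W * ci);
          for (int oh = 0; oh < oH; ++oh) {
            const int ih = oh * stride + dh - pad;
            dst[oh + oH * ow] = (ih >= 0 && ih < H) ? src[ih] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int oH, int oW) {
  for (int ci = 0; ci < C; ++ci) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int k = dh + kh * (dw + kw * ci);
        const double* src = col.colptr(k);
        for (int ow = 0; ow < oW; ++ow) {
          const int iw = ow * stride + dw - pad;
          if (iw < 0 || iw >= W) continue;
          double* dst = x + H * (iw + (std::size_t)W * ci);
          for (int oh = 0; oh < oH; ++oh) {
            const int ih = oh * stride + dh - pad;
            if (ih >= 0 && ih < H) dst[ih] += src[oh + oH * ow];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, const arma::mat& Wm,
                           const arma::vec& bias,
                           int kh, int kw, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if ((int)Wm.n_rows != kh * kw * C) stop("weight/input channel mismatch");
  const int Cout = Wm.n_cols;
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  if (oH < 1 || oW < 1) stop("kernel larger than padded input");
  NumericVector y(( (std::size_t)oH) * oW * Cout * N);
  y.attr("dim") = IntegerVector::create(oH, oW, Cout, N);
  arma::mat col(oH * oW, kh * kw * C);
  const std::size_t xstep = (std::size_t)H * W * C;
  const std::size_t ystep = (std::size_t)oH * oW * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, oH, oW, col);
    arma::mat ymat(y.begin() + n * ystep, oH * oW, Cout, false, true);
    ymat = col * Wm;
    ymat.each_row() += bias.t();
  }
  return y;
}

// Gradient w.r.t. the input of cpp_conv_fwd; also the forward pass of the
// stride-2 transposed convolution (inH/inW then name the *larger* frame).
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, const arma::mat& Wm,
                                int kh, int kw, int stride, int pad,
                                int inH, int inW) {
  IntegerVector d = dims4(dy);
  const int oH = d[0], oW = d[1], Cout = d[2], N = d[3];
  if ((int)Wm.n_cols != Cout) stop("weight/grad channel mismatch");
  const int C = Wm.n_rows / (kh * kw);
  NumericVector dx(((std::size_t)inH) * inW * C * N);
  dx.attr("dim") = IntegerVector::create(inH, inW, C, N);
  const std::size_t xstep = (std::size_t)inH * inW * C;
  const std::size_t ystep = (std::size_t)oH * oW * Cout;
  arma::mat dcol;
  for (int n = 0; n < N; ++n) {
    const arma::mat dymat(dy.begin() + n * ystep, oH * oW, Cout, false, true);
    dcol = dymat * Wm.t();
    col2im_add(dcol, dx.begin() + n * xstep, inH, inW, C,
               kh, kw, stride, pad, oH, oW);
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv_bwd_wb(NumericVector x, NumericVector dy,
                     int kh, int kw, int stride, int pad) {
  IntegerVector dxd = dims4(x), dyd = dims4(dy);
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int oH = dyd[0], oW = dyd[1], Cout = dyd[2];
  if (dyd[3] != N) stop("batch size mismatch");
  arma::mat dW(kh * kw * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(oH * oW, kh * kw * C);
  const std::size_t xstep = (std::size_t)H * W * C;
  const std::size_t ystep = (std::size_t)oH * oW * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, oH, oW, col);
    const arma::mat dymat(dy.begin() + n * ystep, oH * oW, Cout, false, true);
    dW += col.t() * dymat;
    db += arma::sum(dymat, 0).t();
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}
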