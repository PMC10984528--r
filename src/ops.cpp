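// Compiled kernels for the autodiff engine: im2col/GEMM 2-D convolution
// (forward and backward) and batched matrix multiplication. Tensors arrive
// as R double arrays in (H, W, C, N) layout, i.e. column-major with height
// fastest; weights as (K, K, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_side(int in, int k, int d, int stride, int pad) {
  return (in + 2 * pad - d * (k - 1) - 1) / stride + 1;
}

// Fill the im2col matrix (K*K*Cin x Ho*Wo) for one sample.
// Column index = ho + Ho * wo; row index = k1 + K * (k2 + K * c).
static void im2col(const double* x, int H, int W, int C,
                   int K, int d, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int k2 = 0; k2 < K; ++k2) {
      for (int k1 = 0; k1 < K; ++k1) {
        const int row = k1 + K * (k2 + K * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + k2 * d;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)wi * H;
          double* dst = col.colptr(0) + row; // stride between cols = n_rows
          const int base = Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + k1 * d;
            if (hi < 0 || hi >= H) continue;
            dst[(size_t)(base + ho) * col.n_rows] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back into the input gradient (col2im).
static void col2im(const arma::mat& col, int H, int W, int C,
                   int K, int d, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int k2 = 0; k2 < K; ++k2) {
      for (int k1 = 0; k1 < K; ++k1) {
        const int row = k1 + K * (k2 + K * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + k2 * d;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const int base = Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + k1 * d;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += col.at(row, base + ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias,
                                 int dilation, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cout = wdim[3];
  if (wdim[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, wdim[2]);
  const int Ho = out_side(H, K, dilation, stride, pad);
  const int Wo = out_side(W, K, dilation, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: empty output");

  arma::mat wm(const_cast<double*>(w.begin()), (size_t)K * K * C, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat col((size_t)K * K * C, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, dilation, stride, pad,
           Ho, Wo, col);
    arma::mat yn(y.begin() + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    yn = col.t() * wm;
    if (bias.size() > 0) {
      for (int o = 0; o < Cout; ++o) yn.col(o) += bias[o];
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dy,
                         int dilation, int stride, int pad, bool has_bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cout = wdim[3];
  const int Ho = out_side(H, K, dilation, stride, pad);
  const int Wo = out_side(W, K, dilation, stride, pad);

  arma::mat wm(const_cast<double*>(w.begin()), (size_t)K * K * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  NumericVector dw((size_t)K * K * C * Cout);
  NumericVector db(has_bias ? Cout : 0);
  arma::mat dwm(dw.begin(), (size_t)K * K * C, Cout, false, true);
  arma::mat col((size_t)K * K * C, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, dilation, stride, pad,
           Ho, Wo, col);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    dwm += col * dyn;
    if (has_bias) {
      for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dyn.col(o));
    }
    arma::mat dcol = wm * dyn.t();
    col2im(dcol, H, W, C, K, dilation, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batched matrix multiply: a is (m, k, B), b is (k, n, B) (shapes after
// optional transposition), result (m, n, B).
// [[Rcpp::export]]
NumericVector cpp_bmm(NumericVector a, IntegerVector adim,
                      NumericVector b, IntegerVector bdim,
                      bool ta, bool tb) {
  const int B = adim[2];
  if (bdim[2] != B) stop("bmm: batch sizes differ");
  const int am = adim[0], an = adim[1];
  const int bm = bdim[0], bn = bdim[1];
  const int m = ta ? an : am;
  const int kk = ta ? am : an;
  const int k2 = tb ? bn : bm;
  const int n = tb ? bm : bn;
  if (kk != k2) stop("bmm: inner dimensions differ (%d vs %d)", kk, k2);

  NumericVector y((size_t)m * n * B);
  for (int i = 0; i < B; ++i) {
    arma::mat ai(const_cast<double*>(a.begin()) + (size_t)i * am * an, am, an, false, true);
    arma::mat bi(const_cast<double*>(b.begin()) + (size_t)i * bm * bn, bm, bn, false, true);
    arma::mat yi(y.begin() + (size_t)i * m * n, m, n, false, true);
    if (!ta && !tb)      yi = ai * bi;
    else if (ta && !tb)  yi = ai.t() * bi;
    else if (!ta && tb)  yi = ai * bi.t();
    else                 yi = ai.t() * bi.t();
  }
  y.attr("dim") = IntegerVector::create(m, n, B);
  return y;
}
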