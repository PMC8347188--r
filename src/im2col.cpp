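// Convolution kernels for stride-1 2D convolution on (H, W, C) arrays
// stored column-major: patch extraction (im2col) fused with the BLAS
// matrix product.  The patch matrix lives in a static scratch buffer that
// is reused across calls, so per-call allocation is only the (small)
// output.  Padding is `pad_beg` zeros before and `k - 1 - pad_beg` after
// in both spatial dimensions, the only scheme the architecture uses.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// Fill P ((H*W) x (k*k*C)) with patches of x; for a fixed kernel offset
// and channel the source pixels form contiguous runs along the row
// dimension, so the gather is a sequence of memcpy calls.
static void build_patches(const double* xs, int H, int W, int C, int k,
                          int pad_beg, arma::mat& P) {
  const int k2 = k * k;
  P.zeros((size_t)H * W, (size_t)k2 * C);
  double* ps = P.memptr();
  for (int c = 0; c < C; ++c) {
    const double* chan = xs + (size_t)c * H * W;
    for (int b = 0; b < k; ++b) {
      const int dj = b - pad_beg;
      for (int a = 0; a < k; ++a) {
        const int di = a - pad_beg;
        double* out = ps + (size_t)(c * k2 + b * k + a) * H * W;
        const int i0 = di < 0 ? -di : 0;
        const int i1 = di > 0 ? H - di : H;  // exclusive
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(out + (size_t)j * H + i0,
                      chan + (size_t)sj * H + i0 + di,
                      (size_t)(i1 - i0) * sizeof(double));
        }
      }
    }
  }
}

// Z = im2col(x) %*% Wm + bias, returned as (H*W) x Cout.
// [[Rcpp::export]]
NumericMatrix conv_gemm_cpp(NumericVector x, int H, int W, int C,
                            NumericMatrix Wm, NumericVector bias,
                            int k, int pad_beg) {
  static arma::mat P;
  build_patches(x.begin(), H, W, C, k, pad_beg, P);
  const arma::mat Wv(Wm.begin(), Wm.nrow(), Wm.ncol(), false, true);
  NumericMatrix Zout((size_t)H * W, Wm.ncol());
  arma::mat Zv(Zout.begin(), (size_t)H * W, Wm.ncol(), false, true);
  Zv = P * Wv;
  const arma::rowvec bv(bias.begin(), bias.size(), false, true);
  Zv.each_row() += bv;
  return Zout;
}

// dW = t(im2col(x)) %*% dZ, returned as (k*k*C) x Cout.
// [[Rcpp::export]]
NumericMatrix conv_dw_cpp(NumericVector x, int H, int W, int C,
                          NumericMatrix dZ, int k, int pad_beg) {
  static arma::mat P;
  build_patches(x.begin(), H, W, C, k, pad_beg, P);
  const arma::mat dZv(dZ.begin(), dZ.nrow(), dZ.ncol(), false, true);
  NumericMatrix out((size_t)k * k * C, dZ.ncol());
  arma::mat ov(out.begin(), (size_t)k * k * C, dZ.ncol(), false, true);
  ov = P.t() * dZv;
  return out;
}
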