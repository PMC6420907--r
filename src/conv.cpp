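#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Zero-padded, same-size multichannel 2D cross-correlation plus its exact
// adjoint and the kernel cotangent. All three share one blockwise im2col
// (pixels x kh*kw*cin) so the heavy lifting is a BLAS gemm per block; the
// im2col rows are processed in image-column-aligned blocks so each
// (kernel-offset, image-column) pair is one contiguous copy.
// Kernel banks are 4-d arrays (kh, kw, cin, cout), images (H, W, C),
// column-major as in R. Odd kernel sizes only (enforced on the R side).

static const int COL_BLOCK_ELEMS = 1 << 21;   // ~16 MB of doubles per block

static int cols_per_block(int H, int K) {
  int nc = COL_BLOCK_ELEMS / std::max(1, H * K);
  return std::max(1, nc);
}

// Fill rows of A for image columns [j0, j1) of `in` (H x W x cin).
static void im2col_cols(const double* in, int H, int W, int cin,
                        int kh, int kw, int j0, int j1, arma::mat& A) {
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  A.zeros();
  for (int c = 0; c < cin; ++c) {
    const double* plane = in + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int q = a + kh * (b + kw * c);
        double* col = A.colptr(q);
        const int i_lo = std::max(0, ch - a);           // valid output rows
        const int i_hi = std::min(H, H + ch - a);
        for (int j = j0; j < j1; ++j) {
          const int jj = j + b - cw;
          if (jj < 0 || jj >= W) continue;
          if (i_hi > i_lo)
            std::memcpy(col + (size_t)H * (j - j0) + i_lo,
                        plane + (size_t)H * jj + (i_lo + a - ch),
                        sizeof(double) * (i_hi - i_lo));
        }
      }
    }
  }
}

// Adjoint of im2col over image columns [j0, j1): scatter-add into `out`.
static void col2im_cols(const arma::mat& B, double* out, int H, int W,
                        int cin, int kh, int kw, int j0, int j1) {
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  for (int c = 0; c < cin; ++c) {
    double* plane = out + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int q = a + kh * (b + kw * c);
        const double* col = B.colptr(q);
        const int i_lo = std::max(0, ch - a);
        const int i_hi = std::min(H, H + ch - a);
        for (int j = j0; j < j1; ++j) {
          const int jj = j + b - cw;
          if (jj < 0 || jj >= W) continue;
          const double* src = col + (size_t)H * (j - j0) + i_lo;
          double* dst = plane + (size_t)H * jj + (i_lo + a - ch);
          for (int i = 0; i < i_hi - i_lo; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_forward")]]
NumericVector cpp_conv_forward(NumericVector input, NumericVector kernels) {
  IntegerVector di = input.attr("dim"), dk = kernels.attr("dim");
  const int H = di[0], W = di[1], cin = di[2];
  const int kh = dk[0], kw = dk[1], cout = dk[3];
  const int n = H * W, K = kh * kw * cin;
  arma::mat Kmat(kernels.begin(), K, cout, false, true);
  NumericVector out((size_t)n * cout);
  out.attr("dim") = IntegerVector::create(H, W, cout);
  arma::mat O(out.begin(), n, cout, false, true);
  const int jb = cols_per_block(H, K);
  arma::mat A;
  for (int j0 = 0; j0 < W; j0 += jb) {
    const int j1 = std::min(j0 + jb, W);
    A.set_size((size_t)H * (j1 - j0), K);
    im2col_cols(input.begin(), H, W, cin, kh, kw, j0, j1, A);
    O.rows((size_t)H * j0, (size_t)H * j1 - 1) = A * Kmat;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_adjoint")]]
NumericVector cpp_conv_adjoint(NumericVector features, NumericVector kernels) {
  IntegerVector df = features.attr("dim"), dk = kernels.attr("dim");
  const int H = df[0], W = df[1], cout = df[2];
  const int kh = dk[0], kw = dk[1], cin = dk[2];
  const int n = H * W, K = kh * kw * cin;
  arma::mat Kmat(kernels.begin(), K, cout, false, true);
  arma::mat Y(features.begin(), n, cout, false, true);
  NumericVector out((size_t)n * cin);
  out.attr("dim") = IntegerVector::create(H, W, cin);
  const int jb = cols_per_block(H, K);
  for (int j0 = 0; j0 < W; j0 += jb) {
    const int j1 = std::min(j0 + jb, W);
    arma::mat B = Y.rows((size_t)H * j0, (size_t)H * j1 - 1) * Kmat.t();
    col2im_cols(B, out.begin(), H, W, cin, kh, kw, j0, j1);
  }
  return out;
}

// Kernel cotangent of conv_forward: dK = im2col(input)^T * outgrad.
// [[Rcpp::export(name = ".cpp_conv_kernel_grad")]]
NumericVector cpp_conv_kernel_grad(NumericVector input, NumericVector outgrad,
                                   int kh, int kw) {
  IntegerVector di = input.attr("dim"), dg = outgrad.attr("dim");
  const int H = di[0], W = di[1], cin = di[2], cout = dg[2];
  const int n = H * W, K = kh * kw * cin;
  arma::mat Y(outgrad.begin(), n, cout, false, true);
  NumericVector out((size_t)K * cout);
  out.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  arma::mat G(out.begin(), K, cout, false, true);
  const int jb = cols_per_block(H, K);
  arma::mat A;
  for (int j0 = 0; j0 < W; j0 += jb) {
    const int j1 = std::min(j0 + jb, W);
    A.set_size((size_t)H * (j1 - j0), K);
    im2col_cols(input.begin(), H, W, cin, kh, kw, j0, j1, A);
    G += A.t() * Y.rows((size_t)H * j0, (size_t)H * j1 - 1);
  }
  return out;
}
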