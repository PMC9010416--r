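// Convolution primitives for the image-to-force translator.
// Layout: activations are cubes (H, W, C); weights are matrices
// (kh*kw*Cin, Cout) with row index ki + kh*(kj + kw*c), matching the
// column-major flattening of an R array dim (kh, kw, Cin).
// im2col columns are indexed p = oi + oh*oj; the (ki, kj, c) inner loops
// walk both the column buffer and the activation cube contiguously.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int s, int p,
                  int& oh, int& ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  oh = (H + 2 * p - kh) / s + 1;
  ow = (W + 2 * p - kw) / s + 1;
  mat col(kh * kw * C, oh * ow, fill::zeros);
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      double* dst = col.colptr(oi + oh * oj);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * s + kj - p;
          const int base = kh * (kj + kw * c);
          if (wj < 0 || wj >= W) continue;
          const double* src = x.slice_colptr(c, wj);
          const int wi0 = oi * s - p;
          int kiLo = wi0 < 0 ? -wi0 : 0;
          int kiHi = kh;
          if (wi0 + kh > H) kiHi = H - wi0;
          for (int ki = kiLo; ki < kiHi; ++ki)
            dst[base + ki] = src[wi0 + ki];
        }
      }
    }
  }
  return col;
}

static void col2im(const mat& col, int H, int W, int C, int kh, int kw,
                   int s, int p, int oh, int ow, cube& gx) {
  gx.zeros(H, W, C);
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      const double* src = col.colptr(oi + oh * oj);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * s + kj - p;
          const int base = kh * (kj + kw * c);
          if (wj < 0 || wj >= W) continue;
          double* dst = gx.slice_colptr(c, wj);
          const int wi0 = oi * s - p;
          int kiLo = wi0 < 0 ? -wi0 : 0;
          int kiHi = kh;
          if (wi0 + kh > H) kiHi = H - wi0;
          for (int ki = kiLo; ki < kiHi; ++ki)
            dst[wi0 + ki] += src[base + ki];
        }
      }
    }
  }
}

// forward pass; returns the output cube and the column buffer so the
// backward pass can reuse it
// [[Rcpp::export(name = ".convForward")]]
Rcpp::List convForwardCpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  int oh, ow;
  mat col = im2col(x, kh, kw, stride, pad, oh, ow);
  mat y = W.t() * col;               // Cout x P
  y.each_col() += b;
  const int Cout = W.n_cols;
  cube out(oh, ow, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c), oh, ow);
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("col") = col);
}

// [[Rcpp::export(name = ".convBackward")]]
Rcpp::List convBackwardCpp(const arma::mat& col, const arma::mat& W,
                           const arma::cube& gy, int H, int Wd, int C,
                           int kh, int kw, int stride, int pad) {
  const int oh = gy.n_rows, ow = gy.n_cols;
  const int Cout = W.n_cols;
  mat gym(Cout, oh * ow);
  for (int c = 0; c < Cout; ++c)
    gym.row(c) = reshape(gy.slice(c), 1, oh * ow);
  mat gW = col * gym.t();            // K x Cout
  vec gb = sum(gym, 1);
  mat gcol = W * gym;                // K x P
  cube gx;
  col2im(gcol, H, Wd, C, kh, kw, stride, pad, oh, ow, gx);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
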