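// Minimal conv2d primitives (im2col-based) for the compact pix2pix-style
// translator. Tensors are single-sample arma::cube (H x W x C); the weight
// of a conv mapping C -> Cout channels is a (Cout x C*kh*kw) matrix with
// row-major-free fixed layout r = c*kh*kw + kx*kh + ky. Transposed
// convolutions are expressed in R through conv_bwd_data / conv_fwd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// gather input patches into a (C*kh*kw) x (OH*OW) matrix, zero padding
static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int OH, int OW) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(C * kh * kw, OH * OW, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int r = c * kh * kw + kx * kh + ky;
        for (int ox = 0; ox < OW; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < OH; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            cols(r, oy + OH * ox) = xc(iy, ix);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of column gradients back onto the input grid
static cube col2im(const mat& cols, int H, int W, int C, int kh, int kw,
                   int stride, int pad, int OH, int OW) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = dx.slice(c);
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int r = c * kh * kw + kx * kh + ky;
        for (int ox = 0; ox < OW; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < OH; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            xc(iy, ix) += cols(r, oy + OH * ox);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& w,
                    const arma::vec& b, int kh, int kw, int stride, int pad) {
  const int OH = out_size(x.n_rows, kh, stride, pad);
  const int OW = out_size(x.n_cols, kw, stride, pad);
  const int Cout = w.n_rows;
  mat y = w * im2col(x, kh, kw, stride, pad, OH, OW);
  y.each_col() += b;
  cube out(OH, OW, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c), OH, OW);
  return out;
}

// [[Rcpp::export]]
arma::cube conv_bwd_data(const arma::cube& dy, const arma::mat& w,
                         int kh, int kw, int stride, int pad,
                         int H, int W) {
  const int OH = dy.n_rows, OW = dy.n_cols, Cout = dy.n_slices;
  const int C = w.n_cols / (kh * kw);
  mat dym(Cout, OH * OW);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = vectorise(dy.slice(c)).t();
  mat dcols = w.t() * dym;
  return col2im(dcols, H, W, C, kh, kw, stride, pad, OH, OW);
}

// [[Rcpp::export]]
Rcpp::List conv_bwd_weight(const arma::cube& x, const arma::cube& dy,
                           int kh, int kw, int stride, int pad) {
  const int OH = dy.n_rows, OW = dy.n_cols, Cout = dy.n_slices;
  mat cols = im2col(x, kh, kw, stride, pad, OH, OW);
  mat dym(Cout, OH * OW);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = vectorise(dy.slice(c)).t();
  mat dw = dym * cols.t();
  vec db = sum(dym, 1);
  return Rcpp::List::create(Rcpp::Named("dw") = dw, Rcpp::Named("db") = db);
}
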