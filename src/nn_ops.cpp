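// Dense 2-D convolution and max-pooling kernels for small spatial inputs.
//
// Tensor layout throughout: a batch is an R array with dim (C, H, W, N) --
// channel fastest, sample slowest.  Convolution weights are stored as
// (C_in, KH, KW, F): flattened column-major this is exactly the
// (C_in*KH*KW) x F matrix that im2col multiplication needs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold one sample into a (C*KH*KW) x (OH*OW) patch matrix.
// Row index r = c + C*kh + C*KH*kw; column index p = oh + OH*ow.
static void im2col(const double* xp, int C, int H, int W,
                   int KH, int KW, int sh, int sw, int ph, int pw,
                   int OH, int OW, arma::mat& col) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int pcol = oh + OH * ow;
      double* cp = col.colptr(pcol);
      for (int kw = 0; kw < KW; ++kw) {
        const int w_in = ow * sw - pw + kw;
        for (int kh = 0; kh < KH; ++kh) {
          const int h_in = oh * sh - ph + kh;
          double* dst = cp + (std::size_t)C * (kh + KH * kw);
          if (h_in < 0 || h_in >= H || w_in < 0 || w_in >= W) {
            std::memset(dst, 0, C * sizeof(double));
          } else {
            std::memcpy(dst, xp + (std::size_t)C * (h_in + H * w_in),
                        C * sizeof(double));
          }
        }
      }
    }
  }
}

// Scatter-add a patch matrix back onto the (zero-initialised) input plane.
static void col2im(const arma::mat& col, int C, int H, int W,
                   int KH, int KW, int sh, int sw, int ph, int pw,
                   int OH, int OW, double* xp) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int pcol = oh + OH * ow;
      const double* cp = col.colptr(pcol);
      for (int kw = 0; kw < KW; ++kw) {
        const int w_in = ow * sw - pw + kw;
        if (w_in < 0 || w_in >= W) continue;
        for (int kh = 0; kh < KH; ++kh) {
          const int h_in = oh * sh - ph + kh;
          if (h_in < 0 || h_in >= H) continue;
          const double* src = cp + (std::size_t)C * (kh + KH * kw);
          double* dst = xp + (std::size_t)C * (h_in + H * w_in);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");   // C,H,W,N
  IntegerVector wd = w.attr("dim");   // C,KH,KW,F
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int KH = wd[1], KW = wd[2], F = wd[3];
  if (wd[0] != C) stop("conv2d: input channels (%d) != weight channels (%d)", C, wd[0]);
  const int OH = (H + 2 * ph - KH) / sh + 1;
  const int OW = (W + 2 * pw - KW) / sw + 1;
  if (OH < 1 || OW < 1) stop("conv2d: output size would be empty");

  const arma::mat wmat(const_cast<double*>(w.begin()), C * KH * KW, F, false, true);
  NumericVector out((R_xlen_t)F * OH * OW * N);
  out.attr("dim") = IntegerVector::create(F, OH, OW, N);

  arma::mat col(C * KH * KW, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)C * H * W * n,
           C, H, W, KH, KW, sh, sw, ph, pw, OH, OW, col);
    arma::mat o(out.begin() + (std::size_t)F * OH * OW * n, F, OH * OW, false, true);
    o = wmat.t() * col;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector od = dout.attr("dim");  // F,OH,OW,N
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int KH = wd[1], KW = wd[2], F = wd[3];
  const int OH = od[1], OW = od[2];

  const arma::mat wmat(const_cast<double*>(w.begin()), C * KH * KW, F, false, true);
  NumericVector dx((R_xlen_t)C * H * W * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)C * KH * KW * F);
  dw.attr("dim") = wd;
  arma::mat dwmat(dw.begin(), C * KH * KW, F, false, true);

  arma::mat col(C * KH * KW, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)C * H * W * n,
           C, H, W, KH, KW, sh, sw, ph, pw, OH, OW, col);
    const arma::mat dom(const_cast<double*>(dout.begin()) + (std::size_t)F * OH * OW * n,
                        F, OH * OW, false, true);
    dwmat += col * dom.t();
    arma::mat dcol = wmat * dom;   // K x P
    col2im(dcol, C, H, W, KH, KW, sh, sw, ph, pw, OH, OW,
           dx.begin() + (std::size_t)C * H * W * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with implicit -Inf padding (matches the usual CNN convention).
// Returns the pooled output and, per output cell, the 0-based linear offset
// (c + C*h + C*H*w) of the winning input cell within its sample.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int kh, int kw,
                     int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;

  NumericVector out((R_xlen_t)C * OH * OW * N);
  out.attr("dim") = IntegerVector::create(C, OH, OW, N);
  IntegerVector idx((R_xlen_t)C * OH * OW * N);
  idx.attr("dim") = IntegerVector::create(C, OH, OW, N);

  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (std::size_t)C * H * W * n;
    double* op = out.begin() + (std::size_t)C * OH * OW * n;
    int* ip = idx.begin() + (std::size_t)C * OH * OW * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int besti = -1;
          for (int dw2 = 0; dw2 < kw; ++dw2) {
            const int w_in = ow * sw - pw + dw2;
            if (w_in < 0 || w_in >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int h_in = oh * sh - ph + dh;
              if (h_in < 0 || h_in >= H) continue;
              const int off = c + C * (h_in + H * w_in);
              if (xp[off] > best) { best = xp[off]; besti = off; }
            }
          }
          const std::size_t o = c + (std::size_t)C * (oh + OH * ow);
          op[o] = best;
          ip[o] = besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx,
                              IntegerVector xdim) {
  IntegerVector od = dout.attr("dim");  // C,OH,OW,N
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const std::size_t per_out = (std::size_t)od[0] * od[1] * od[2];
  NumericVector dx((R_xlen_t)C * H * W * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* dop = dout.begin() + per_out * n;
    const int* ip = idx.begin() + per_out * n;
    double* dxp = dx.begin() + (std::size_t)C * H * W * n;
    for (std::size_t i = 0; i < per_out; ++i)
      if (ip[i] >= 0) dxp[ip[i]] += dop[i];
  }
  return dx;
}
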