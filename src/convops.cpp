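// Stride-1 "same"-padded 2D convolution kernels used by the autodiff core.
// Layout follows R column-major arrays: images are (H, W, C, N), weights are
// (kh, kw, Cin, Cout).  im2col + GEMM so the heavy lifting is BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int ph, int pw, arma::mat& col) {
  // col is (kh*kw*C) x (H*W); row index r = ih + kh*iw + kh*kw*c
  const int P = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * P;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        const int r = ih + kh * iw + kh * kw * c;
        double* colr = col.memptr() + r;  // stride = col.n_rows
        const int K = col.n_rows;
        for (int ow = 0; ow < W; ++ow) {
          const int sw = ow + iw - pw;
          for (int oh = 0; oh < H; ++oh) {
            const int sh = oh + ih - ph;
            double v = 0.0;
            if (sh >= 0 && sh < H && sw >= 0 && sw < W)
              v = xc[sh + (size_t)H * sw];
            colr[(size_t)K * (oh + (size_t)H * ow)] = v;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const arma::mat& col, int H, int W, int C,
                              int kh, int kw, int ph, int pw, double* gx) {
  const int P = H * W;
  const int K = col.n_rows;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * P;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        const int r = ih + kh * iw + kh * kw * c;
        const double* colr = col.memptr() + r;
        for (int ow = 0; ow < W; ++ow) {
          const int sw = ow + iw - pw;
          if (sw < 0 || sw >= W) continue;
          for (int oh = 0; oh < H; ++oh) {
            const int sh = oh + ih - ph;
            if (sh < 0 || sh >= H) continue;
            gc[sh + (size_t)H * sw] += colr[(size_t)K * (oh + (size_t)H * ow)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int P = H * W, K = kh * kw * C;

  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * P * C, H, W, C, kh, kw, ph, pw, col);
    arma::mat Y(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    Y = col.t() * Wm;            // (P x Cout)
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int P = H * W, K = kh * kw * C;

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((size_t)kh * kw * C * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector gb(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::vec Gb(gb.begin(), Cout, false, true);
  arma::mat col(K, P);

  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * P * Cout,
                 P, Cout, false, true);
    im2col(x.begin() + (size_t)n * P * C, H, W, C, kh, kw, ph, pw, col);
    Gw += col * Gy;                       // K x Cout
    Gb += arma::sum(Gy, 0).t();
    arma::mat dcol = Wm * Gy.t();         // K x P
    col2im_add(dcol, H, W, C, kh, kw, ph, pw, gx.begin() + (size_t)n * P * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
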