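// Convolutional building blocks for the periodic U-Net surrogate.
//
// Tensors are column-major R arrays: images (H, W, C); convolution weights
// (kh, kw, Cin, Cout).  All convolutions are 'same'-size with circular
// (periodic) padding, matching the torus topology of the lattice.
// Implemented as im2col + GEMM so the BLAS does the heavy lifting.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {
inline int wrap(int i, int n) { return i < 0 ? i + n : (i >= n ? i - n : i); }

void im2col_circ(const double* x, int H, int W, int C, int kh, int kw,
                 arma::mat& Xc) {
  // Xc: (H*W) x (kh*kw*C); column q = ki + kh*(kj + kw*cin)
  const int oh = kh / 2, ow = kw / 2;
  for (int cin = 0; cin < C; ++cin)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * cin);
        double* col = Xc.colptr(q);
        const double* xc = x + (size_t)H * W * cin;
        int di = ki - oh, dj = kj - ow;
        for (int c = 0; c < W; ++c) {
          int c2 = wrap(c + dj, W);
          const double* src = xc + (size_t)H * c2;
          double* dst = col + (size_t)H * c;
          for (int r = 0; r < H; ++r) dst[r] = src[wrap(r + di, H)];
        }
      }
}
} // namespace

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(const NumericVector& x, const NumericVector& w,
                           const NumericVector& b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch (%d vs %d)", Cin, C);
  arma::mat Xc((size_t)H * W, (size_t)kh * kw * C);
  im2col_circ(x.begin(), H, W, C, kh, kw, Xc);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat Y = Xc * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const NumericVector& x, const NumericVector& w,
                  const NumericVector& dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int oh = kh / 2, ow = kw / 2;
  arma::mat Xc((size_t)H * W, (size_t)kh * kw * C);
  im2col_circ(x.begin(), H, W, C, kh, kw, Xc);
  arma::mat dY(const_cast<double*>(dy.begin()), (size_t)H * W, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);

  arma::mat dW = Xc.t() * dY;                    // (khkwC x Cout)
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dXc = dY * Wm.t();                   // (HW x khkwC)

  NumericVector dx((size_t)H * W * C);
  double* dxp = dx.begin();
  for (int cin = 0; cin < C; ++cin)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * cin);
        const double* col = dXc.colptr(q);
        double* xc = dxp + (size_t)H * W * cin;
        int di = ki - oh, dj = kj - ow;
        for (int c = 0; c < W; ++c) {
          int c2 = wrap(c + dj, W);
          double* dst = xc + (size_t)H * c2;
          const double* src = col + (size_t)H * c;
          for (int r = 0; r < H; ++r) dst[wrap(r + di, H)] += src[r];
        }
      }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2.  Returns pooled values and the linear index of
// the argmax inside the input plane (1-based, for the backward scatter).
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  if (H % 2 || W % 2) stop("maxpool: odd spatial size");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)H * W * ch;
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        size_t best = (size_t)(2 * r) + (size_t)H * (2 * c);
        double bv = xc[best];
        size_t cand[3] = {best + 1, best + H, best + H + 1};
        for (int k = 0; k < 3; ++k)
          if (xc[cand[k]] > bv) { bv = xc[cand[k]]; best = cand[k]; }
        size_t o = (size_t)r + (size_t)Ho * c + (size_t)Ho * Wo * ch;
        y[o] = bv;
        idx[o] = (int)(best + (size_t)H * W * ch) + 1;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dy, const IntegerVector& idx,
                              int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int C = yd[2];
  NumericVector dx((size_t)H * W * C);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Nearest-neighbor 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  NumericVector y((size_t)4 * H * W * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = xp[(size_t)r + (size_t)H * c + (size_t)H * W * ch];
        size_t base = (size_t)(2 * r) + (size_t)(2 * H) * (2 * c) +
                      (size_t)4 * H * W * ch;
        yp[base] = v; yp[base + 1] = v;
        yp[base + 2 * H] = v; yp[base + 2 * H + 1] = v;
      }
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(const NumericVector& dy) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C);
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t base = (size_t)(2 * r) + (size_t)H2 * (2 * c) + (size_t)H2 * W2 * ch;
        xp[(size_t)r + (size_t)H * c + (size_t)H * W * ch] =
            dp[base] + dp[base + 1] + dp[base + H2] + dp[base + H2 + 1];
      }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
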