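// Compiled kernels for the minimal NN engine: im2col-based 2-D convolution
// (forward + backward) and max pooling with argmax caching.
//
// Tensor layout everywhere: column-major R arrays dim (H, W, C, B).
// Weight layout: (k, k, Cin, Cout). Flattening the first three weight dims
// column-major gives the GEMM row index r = kh + k*kw + k*k*c, which is the
// same ordering the im2col patch matrix uses.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* xp, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  // col is (k*k*C) x (Ho*Wo), pre-allocated; zero-padding handled by zeroing.
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      double* cp = col.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w0 + kw;
          if (ww < 0 || ww >= W) continue;
          const double* xcol = xp + (size_t)H * (ww + (size_t)W * c);
          double* dst = cp + k * (kw + k * c);
          for (int kh = 0; kh < k; ++kh) {
            const int hh = h0 + kh;
            if (hh >= 0 && hh < H) dst[kh] = xcol[hh];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& dcol, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo,
                       double* dxp) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const double* cp = dcol.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w0 + kw;
          if (ww < 0 || ww >= W) continue;
          double* xcol = dxp + (size_t)H * (ww + (size_t)W * c);
          const double* src = cp + k * (kw + k * c);
          for (int kh = 0; kh < k; ++kh) {
            const int hh = h0 + kh;
            if (hh >= 0 && hh < H) xcol[hh] += src[kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, wd[2]);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int M = k * k * C, P = Ho * Wo;

  const arma::mat Wmat(const_cast<double*>(w.begin()), M, Cout, false, true);
  NumericVector y((R_xlen_t)P * Cout * B);
  arma::mat col(M, P);
  const bool hasb = bias.size() > 0;
  arma::rowvec bv;
  if (hasb) bv = arma::rowvec(const_cast<double*>(bias.begin()), Cout, false, true);

  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat Y = col.t() * Wmat;            // P x Cout
    if (hasb) Y.each_row() += bv;
    std::memcpy(y.begin() + (size_t)P * Cout * b, Y.memptr(),
                sizeof(double) * (size_t)P * Cout);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector dy, int stride, int pad, bool hasb) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int M = k * k * C, P = Ho * Wo;

  const arma::mat Wmat(const_cast<double*>(w.begin()), M, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * B);
  NumericVector dwv((R_xlen_t)M * Cout);
  arma::mat dW(dwv.begin(), M, Cout, false, true);
  NumericVector dbv(hasb ? Cout : 0);
  arma::mat col(M, P);

  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, k, stride, pad, Ho, Wo, col);
    const arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)P * Cout * b,
                       P, Cout, false, true);
    dW += col * dY;                           // M x Cout
    arma::mat dcol = Wmat * dY.t();           // M x P
    col2im_add(dcol, H, W, C, k, stride, pad, Ho, Wo,
               dx.begin() + (size_t)H * W * C * b);
    if (hasb) {
      arma::rowvec s = arma::sum(dY, 0);
      for (int o = 0; o < Cout; ++o) dbv[o] += s[o];
    }
  }
  dx.attr("dim") = xd;
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector xd,
                     int k, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("maxpool: non-positive output size");
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * B); // 0-based flat index into x
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * (size_t)W * (c + (size_t)C * b);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          double best = R_NegInf; long besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int ww = w0 + kw;
            if (ww < 0 || ww >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hh = h0 + kh;
              if (hh < 0 || hh >= H) continue;
              const double v = xp[base + hh + (size_t)H * ww];
              if (v > best) { best = v; besti = (long)(base + hh + (size_t)H * ww); }
            }
          }
          // position (ho, wo, c, b) in output, column-major
          const R_xlen_t oi = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * b));
          y[oi] = best; idx[oi] = (int)besti;
          ++o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector dy,
                              IntegerVector xd) {
  NumericVector dx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xd;
  return dx;
}
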