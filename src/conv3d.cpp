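// 3D convolution via im2col + GEMM. Volumes are R arrays with dim
// (H, W, D, C) (column-major, channel slowest); kernels have dim
// (k, k, k, Cin, Cout). Zero padding `pad`, isotropic stride `stride`.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Patch matrix: rows index output positions (h fastest), columns index
// (kh, kw, kd, cin) in R's column-major flattening of the kernel array.
static arma::mat im2col3(const double* x, int H, int W, int D, int C,
                         int k, int s, int p, int Ho, int Wo, int Do) {
  const arma::uword npos = (arma::uword)Ho * Wo * Do;
  arma::mat P(npos, (arma::uword)k * k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * D * c;
    for (int kd = 0; kd < k; ++kd)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const arma::uword col =
              (arma::uword)kh + k * ((arma::uword)kw + k * ((arma::uword)kd + k * (arma::uword)c));
          double* Pc = P.colptr(col);
          for (int dd = 0; dd < Do; ++dd) {
            int d = dd * s + kd - p;
            if (d < 0 || d >= D) continue;
            for (int ww = 0; ww < Wo; ++ww) {
              int w = ww * s + kw - p;
              if (w < 0 || w >= W) continue;
              const double* src = xc + (size_t)H * (w + (size_t)W * d);
              double* dst = Pc + (size_t)Ho * (ww + (size_t)Wo * dd);
              for (int hh = 0; hh < Ho; ++hh) {
                int h = hh * s + kh - p;
                if (h < 0 || h >= H) continue;
                dst[hh] = src[h];
              }
            }
          }
        }
  }
  return P;
}

// Scatter-add transpose of im2col3.
static void col2im3(const arma::mat& P, double* x, int H, int W, int D, int C,
                    int k, int s, int p, int Ho, int Wo, int Do) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * D * c;
    for (int kd = 0; kd < k; ++kd)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const arma::uword col =
              (arma::uword)kh + k * ((arma::uword)kw + k * ((arma::uword)kd + k * (arma::uword)c));
          const double* Pc = P.colptr(col);
          for (int dd = 0; dd < Do; ++dd) {
            int d = dd * s + kd - p;
            if (d < 0 || d >= D) continue;
            for (int ww = 0; ww < Wo; ++ww) {
              int w = ww * s + kw - p;
              if (w < 0 || w >= W) continue;
              double* dst = xc + (size_t)H * (w + (size_t)W * d);
              const double* src = Pc + (size_t)Ho * (ww + (size_t)Wo * dd);
              for (int hh = 0; hh < Ho; ++hh) {
                int h = hh * s + kh - p;
                if (h < 0 || h >= H) continue;
                dst[h] += src[hh];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: input has %d channels but kernel expects %d", C, Cin);
  int Ho = out_len(H, k, stride, pad), Wo = out_len(W, k, stride, pad),
      Do = out_len(D, k, stride, pad);
  if (Ho < 1 || Wo < 1 || Do < 1)
    stop("conv3d: output would be empty (grid smaller than the kernel's receptive field)");
  arma::mat P = im2col3(x.begin(), H, W, D, C, k, stride, pad, Ho, Wo, Do);
  arma::mat Wm(w.begin(), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat Y = P * Wm;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Do, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  int k = wd[0], Cin = wd[3], Cout = wd[4];
  int Ho = yd[0], Wo = yd[1], Do = yd[2];
  arma::mat P = im2col3(x.begin(), H, W, D, C, k, stride, pad, Ho, Wo, Do);
  arma::mat dY(dy.begin(), (arma::uword)Ho * Wo * Do, Cout, false, true);
  arma::mat Wm(w.begin(), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat dW = P.t() * dY;
  arma::mat dP = dY * Wm.t();
  NumericVector dx((size_t)H * W * D * C);
  col2im3(dP, dx.begin(), H, W, D, C, k, stride, pad, Ho, Wo, Do);
  dx.attr("dim") = IntegerVector::create(H, W, D, C);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv);
}
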