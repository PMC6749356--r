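// 2D valid convolution forward/backward for the CNN training engine.
// Layout convention (R column-major arrays):
//   activations: dim (H, W, C, B)
//   kernels:     dim (kh, kw, Cin, Cout)
// im2col row order: r = c*kh*kw + kj*kh + ki  (ki fastest), matching the
// reshaped kernel matrix, so each layer is one GEMM per sample.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int Ho, int Wo, arma::mat& col) {
  // col: (Cin*kh*kw) x (Ho*Wo)
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int p = j * Ho + i;
        double* dst = col.colptr(p) + c * kh * kw;
        for (int kj = 0; kj < kw; ++kj) {
          const double* src = xc + (size_t)(j + kj) * H + i;
          for (int ki = 0; ki < kh; ++ki) dst[kj * kh + ki] = src[ki];
        }
      }
    }
  }
}

static arma::mat kernel_matrix(const NumericVector& w, int kh, int kw,
                               int Cin, int Cout) {
  // (Cout) x (Cin*kh*kw); kernel array index ki + kh*(kj + kw*(c + Cin*o))
  arma::mat wm(Cout, Cin * kh * kw);
  const double* wp = REAL(w);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          wm(o, c * kh * kw + kj * kh + ki) =
            wp[ki + (size_t)kh * (kj + (size_t)kw * (c + (size_t)Cin * o))];
  return wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector bias) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  if (wdim[2] != Cin) stop("kernel channel count does not match input");
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel");

  arma::mat wm = kernel_matrix(w, kh, kw, Cin, Cout);
  arma::vec bv(REAL(bias), Cout);
  NumericVector y((size_t)Ho * Wo * Cout * B);
  arma::mat col(Cin * kh * kw, Ho * Wo);

  for (int b = 0; b < B; ++b) {
    im2col(REAL(x) + (size_t)b * H * W * Cin, H, W, Cin, kh, kw, Ho, Wo, col);
    arma::mat out = wm * col;            // Cout x (Ho*Wo)
    out.each_col() += bv;
    double* yp = REAL(y) + (size_t)b * Ho * Wo * Cout;
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + (size_t)o * Ho * Wo] = out(o, p);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector dy) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = H - kh + 1, Wo = W - kw + 1;

  arma::mat wm = kernel_matrix(w, kh, kw, Cin, Cout);
  arma::mat dwm(Cout, Cin * kh * kw, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((size_t)H * W * Cin * B);
  arma::mat col(Cin * kh * kw, Ho * Wo);

  for (int b = 0; b < B; ++b) {
    im2col(REAL(x) + (size_t)b * H * W * Cin, H, W, Cin, kh, kw, Ho, Wo, col);
    // dY for this sample as (Cout x Ho*Wo)
    arma::mat dym(Cout, Ho * Wo);
    const double* dyp = REAL(dy) + (size_t)b * Ho * Wo * Cout;
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < Ho * Wo; ++p) dym(o, p) = dyp[p + (size_t)o * Ho * Wo];

    dwm += dym * col.t();
    db += arma::sum(dym, 1);

    arma::mat dcol = wm.t() * dym;       // (Cin*kh*kw) x (Ho*Wo)
    double* dxp = REAL(dx) + (size_t)b * H * W * Cin;
    for (int c = 0; c < Cin; ++c) {
      double* dxc = dxp + (size_t)c * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int p = j * Ho + i;
          const double* src = dcol.colptr(p) + c * kh * kw;
          for (int kj = 0; kj < kw; ++kj) {
            double* dst = dxc + (size_t)(j + kj) * H + i;
            for (int ki = 0; ki < kh; ++ki) dst[ki] += src[kj * kh + ki];
          }
        }
      }
    }
  }

  // repack dW into kernel array layout
  NumericVector dw((size_t)kh * kw * Cin * Cout);
  double* dwp = REAL(dw);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dwp[ki + (size_t)kh * (kj + (size_t)kw * (c + (size_t)Cin * o))] =
            dwm(o, c * kh * kw + kj * kh + ki);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, B);

  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
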