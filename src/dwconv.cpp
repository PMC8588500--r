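// Depthwise 3x3 'same' convolution kernels for the stage-2 network.
// Feature maps are (H, W, B, C) column-major arrays; the depthwise kernel
// is (3, 3, C). These are the only hot loops not expressible as one BLAS
// call, hence the compiled implementation.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector dw_conv_fwd_cpp(NumericVector x, NumericVector w,
                              IntegerVector dims) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  NumericVector out(x.size());
  const double *xp = x.begin(), *wp = w.begin();
  double *op = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double *wc = wp + 9 * c;
    for (int b = 0; b < B; ++b) {
      const double *xs = xp + ((R_xlen_t)c * B + b) * planeHW;
      double *os = op + ((R_xlen_t)c * B + b) * planeHW;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double wv = wc[(di + 1) + 3 * (dj + 1)];
          if (wv == 0.0) continue;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xs + (R_xlen_t)(j + dj) * H + di;
            double *ocol = os + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) ocol[i] += wv * xcol[i];
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List dw_conv_bwd_cpp(NumericVector x, NumericVector dout, NumericVector w,
                     IntegerVector dims, bool need_dx) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  NumericVector dw(9 * C);
  NumericVector dx(need_dx ? x.size() : 0);
  const double *xp = x.begin(), *dp = dout.begin(), *wp = w.begin();
  double *dwp = dw.begin();
  double *dxp = need_dx ? dx.begin() : nullptr;
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double *wc = wp + 9 * c;
    double *dwc = dwp + 9 * c;
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base = ((R_xlen_t)c * B + b) * planeHW;
      const double *xs = xp + base;
      const double *ds = dp + base;
      double *dxs = need_dx ? dxp + base : nullptr;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double wv = wc[(di + 1) + 3 * (dj + 1)];
          double acc = 0.0;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xs + (R_xlen_t)(j + dj) * H + di;
            const double *dcol = ds + (R_xlen_t)j * H;
            double *dxcol = need_dx ? dxs + (R_xlen_t)(j + dj) * H + di : nullptr;
            for (int i = i0; i < i1; ++i) {
              acc += xcol[i] * dcol[i];
              if (need_dx) dxcol[i] += wv * dcol[i];
            }
          }
          dwc[(di + 1) + 3 * (dj + 1)] += acc;
        }
      }
    }
  }
  if (need_dx) dx.attr("dim") = dims;
  NumericVector dwa = dw;
  dwa.attr("dim") = IntegerVector::create(3, 3, C);
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dwa);
}
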