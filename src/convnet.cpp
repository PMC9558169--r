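#include <Rcpp.h>
using namespace Rcpp;

// Minimal dense 2-D convolution kernels (NCHW-free: R arrays are H x W x C,
// column-major) used by the encoder-decoder segmenter. "Same" zero padding;
// dilation supported for the atrous pyramid. Single-threaded, deterministic.

// x: H x W x Cin, w: k x k x Cin x Cout (flat, column-major), b: Cout
// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int H, int W, int Cin, int Cout, int k, int dil) {
  int pad = dil * (k - 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bias = b[co];
    for (int wcol = 0; wcol < W; ++wcol)
      for (int h = 0; h < H; ++h)
        yp[h + H * wcol + H * W * co] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          double wv = wp[ki + k * kj + k * k * ci + k * k * Cin * co];
          if (wv == 0.0) continue;
          int dh = ki * dil - pad, dw = kj * dil - pad;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int wc = w0; wc < w1; ++wc) {
            const double *xcol = xp + (wc + dw) * H + static_cast<R_xlen_t>(H) * W * ci + dh;
            double *ycol = yp + wc * H + static_cast<R_xlen_t>(H) * W * co;
            for (int h = h0; h < h1; ++h) ycol[h] += wv * xcol[h];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  return y;
}

// gradient wrt input, weights and bias; gy: H x W x Cout
// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int H, int W, int Cin, int Cout, int k, int dil) {
  int pad = dil * (k - 1) / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Cin);
  NumericVector gw(static_cast<R_xlen_t>(k) * k * Cin * Cout);
  NumericVector gb(Cout);
  const double *xp = x.begin(), *wp = w.begin(), *gyp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gyc = gyp + static_cast<R_xlen_t>(H) * W * co;
    double s = 0.0;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(H) * W; ++i) s += gyc[i];
    gb[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int dh = ki * dil - pad, dw = kj * dil - pad;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          double wv = wp[ki + k * kj + k * k * ci + k * k * Cin * co];
          double acc = 0.0;
          for (int wc = w0; wc < w1; ++wc) {
            const double *xcol = xp + (wc + dw) * H + static_cast<R_xlen_t>(H) * W * ci + dh;
            const double *gcol = gyc + wc * H;
            double *gxcol = gxp + (wc + dw) * H + static_cast<R_xlen_t>(H) * W * ci + dh;
            for (int h = h0; h < h1; ++h) {
              acc += gcol[h] * xcol[h];
              gxcol[h] += wv * gcol[h];
            }
          }
          gwp[ki + k * kj + k * k * ci + k * k * Cin * co] += acc;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 average pooling; H and W must be even
// [[Rcpp::export]]
NumericVector avgpool2_fw(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double *b = xp + 2 * h + 2 * w * H + static_cast<R_xlen_t>(H) * W * c;
        yp[h + Ho * w + static_cast<R_xlen_t>(Ho) * Wo * c] =
          0.25 * (b[0] + b[1] + b[H] + b[H + 1]);
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bw(NumericVector gy, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  const double *gp = gy.begin();
  double *xp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double g = 0.25 * gp[h + Ho * w + static_cast<R_xlen_t>(Ho) * Wo * c];
        double *b = xp + 2 * h + 2 * w * H + static_cast<R_xlen_t>(H) * W * c;
        b[0] += g; b[1] += g; b[H] += g; b[H + 1] += g;
      }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
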