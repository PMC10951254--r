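// Convolution and resampling kernels for the network engine.
// Tensor layout everywhere: R arrays of dim (H, W, C, N), column-major,
// so the linear index is h + H*(w + W*(c + C*n)).
// Convolution weights: dim (k, k, C_in/groups, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix for one group over all images.
// A has dim (Ho*Wo*N) x (k*k*Cpg); rows ordered ho fastest, then wo, then n.
// Columns ordered kh fastest, then kw, then local channel.
static void im2col_group(const double* x, arma::mat& A,
                         int H, int W, int C, int N,
                         int k, int stride, int pad,
                         int c0, int Cpg, int Ho, int Wo) {
  const int HoWo = Ho * Wo;
  for (int cl = 0; cl < Cpg; ++cl) {
    const double* xc = x + (size_t)(c0 + cl) * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = cl * k * k + kw * k + kh;
        double* Acol = A.colptr(col);
        // valid output range along h for this kernel row
        int ho_lo = 0;
        while (ho_lo * stride + kh - pad < 0) ++ho_lo;
        int ho_hi = Ho - 1;
        while (ho_hi >= 0 && ho_hi * stride + kh - pad >= H) --ho_hi;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (size_t)n * H * W * C;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            double* dst = Acol + (size_t)n * HoWo + (size_t)wo * Ho;
            if (wi < 0 || wi >= W) {
              std::fill(dst, dst + Ho, 0.0);
              continue;
            }
            const double* src = xn + (size_t)wi * H + (kh - pad);
            for (int ho = 0; ho < ho_lo; ++ho) dst[ho] = 0.0;
            if (stride == 1) {
              if (ho_hi >= ho_lo)
                std::copy(src + ho_lo, src + ho_hi + 1, dst + ho_lo);
            } else {
              for (int ho = ho_lo; ho <= ho_hi; ++ho)
                dst[ho] = src[(size_t)ho * stride];
            }
            for (int ho = ho_hi + 1; ho < Ho; ++ho) dst[ho] = 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back to the input gradient (col2im).
static void col2im_group(const arma::mat& dA, double* dx,
                         int H, int W, int C, int N,
                         int k, int stride, int pad,
                         int c0, int Cpg, int Ho, int Wo) {
  const int HoWo = Ho * Wo;
  for (int cl = 0; cl < Cpg; ++cl) {
    double* xc = dx + (size_t)(c0 + cl) * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = cl * k * k + kw * k + kh;
        const double* Acol = dA.colptr(col);
        int ho_lo = 0;
        while (ho_lo * stride + kh - pad < 0) ++ho_lo;
        int ho_hi = Ho - 1;
        while (ho_hi >= 0 && ho_hi * stride + kh - pad >= H) --ho_hi;
        for (int n = 0; n < N; ++n) {
          double* xn = xc + (size_t)n * H * W * C;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            const double* src = Acol + (size_t)n * HoWo + (size_t)wo * Ho;
            double* dst = xn + (size_t)wi * H + (kh - pad);
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[(size_t)ho * stride] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cpg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cpg * groups) stop("channel/group mismatch");
  const int Coutpg = Cout / groups;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv output would be empty");

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cpg, Cout,
                     false, true);
  const int HoWo = Ho * Wo;
  arma::mat A((size_t)HoWo * N, (size_t)k * k * Cpg);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), A, H, W, C, N, k, stride, pad, g * Cpg, Cpg, Ho, Wo);
    arma::mat Y = A * Wm.cols(g * Coutpg, (g + 1) * Coutpg - 1);
    // Y(row, c_local): rows (ho, wo, n); copy into (Ho, Wo, c, N) layout.
    for (int cl = 0; cl < Coutpg; ++cl) {
      const double* src = Y.colptr(cl);
      double* dst = y.begin() + (size_t)(g * Coutpg + cl) * HoWo;
      for (int n = 0; n < N; ++n)
        std::copy(src + (size_t)n * HoWo, src + (size_t)(n + 1) * HoWo,
                  dst + (size_t)n * HoWo * Cout);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, int groups, bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cpg = wd[2], Cout = wd[3];
  const int Coutpg = Cout / groups;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int HoWo = Ho * Wo;

  NumericVector dx(need_dx ? (size_t)H * W * C * N : 1);
  if (need_dx) dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * Cpg * Cout);
  dw.attr("dim") = wd;

  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cpg, Cout,
                     false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cpg, Cout, false, true);
  arma::mat A((size_t)HoWo * N, (size_t)k * k * Cpg);
  arma::mat dY((size_t)HoWo * N, Coutpg);

  for (int g = 0; g < groups; ++g) {
    // gather dY for this group's output channels into (ho,wo,n) x c_local
    for (int cl = 0; cl < Coutpg; ++cl) {
      double* dst = dY.colptr(cl);
      const double* src = dy.begin() + (size_t)(g * Coutpg + cl) * HoWo;
      for (int n = 0; n < N; ++n)
        std::copy(src + (size_t)n * HoWo * Cout,
                  src + (size_t)n * HoWo * Cout + HoWo, dst + (size_t)n * HoWo);
    }
    im2col_group(x.begin(), A, H, W, C, N, k, stride, pad, g * Cpg, Cpg, Ho, Wo);
    dWm.cols(g * Coutpg, (g + 1) * Coutpg - 1) = A.t() * dY;
    if (need_dx) {
      arma::mat dA = dY * Wm.cols(g * Coutpg, (g + 1) * Coutpg - 1).t();
      col2im_group(dA, dx.begin(), H, W, C, N, k, stride, pad, g * Cpg, Cpg,
                   Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Bilinear x2 upsampling (half-pixel centers, clamped borders).
// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)cn * H * W;
    double* ys = y.begin() + (size_t)cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double sw = (wo + 0.5) / 2.0 - 0.5;
      int w0 = (int)std::floor(sw);
      const double tw = sw - w0;
      int w1 = std::min(w0 + 1, W - 1); w0 = std::max(w0, 0);
      const double* c0 = xs + (size_t)w0 * H;
      const double* c1 = xs + (size_t)w1 * H;
      double* yc = ys + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const double sh = (ho + 0.5) / 2.0 - 0.5;
        int h0 = (int)std::floor(sh);
        const double th = sh - h0;
        int h1 = std::min(h0 + 1, H - 1); h0 = std::max(h0, 0);
        yc[ho] = (1 - th) * (1 - tw) * c0[h0] + th * (1 - tw) * c0[h1]
               + (1 - th) * tw * c1[h0] + th * tw * c1[h1];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* ys = dy.begin() + (size_t)cn * Ho * Wo;
    double* xs = dx.begin() + (size_t)cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const double sw = (wo + 0.5) / 2.0 - 0.5;
      int w0 = (int)std::floor(sw);
      const double tw = sw - w0;
      int w1 = std::min(w0 + 1, W - 1); w0 = std::max(w0, 0);
      double* c0 = xs + (size_t)w0 * H;
      double* c1 = xs + (size_t)w1 * H;
      const double* yc = ys + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const double sh = (ho + 0.5) / 2.0 - 0.5;
        int h0 = (int)std::floor(sh);
        const double th = sh - h0;
        int h1 = std::min(h0 + 1, H - 1); h0 = std::max(h0, 0);
        const double g = yc[ho];
        c0[h0] += (1 - th) * (1 - tw) * g;
        c0[h1] += th * (1 - tw) * g;
        c1[h0] += (1 - th) * tw * g;
        c1[h1] += th * tw * g;
      }
    }
  }
  return dx;
}
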