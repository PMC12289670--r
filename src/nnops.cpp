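// Low-level dense kernels for the detector: grouped 2-D convolution
// (forward / backward via im2col + BLAS) and max pooling.
//
// Array layout convention (matches the R side): feature maps are numeric
// arrays with dim = (H, W, C, N), column-major. Convolution weights are
// arrays with dim = (KH, KW, Cin/groups, Cout). All kernels assume odd
// kernel sizes with symmetric zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Gather the im2col matrix for one image and one channel group.
// col has (KH*KW*Cg) rows and (HO*WO) cols; row index kh + KH*kw + KH*KW*c
// matches the column-major flattening of the (KH, KW, Cg, .) weight array.
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int KH, int KW, int sh, int sw, int ph, int pw,
                   int HO, int WO, arma::mat& col) {
  for (int c = 0; c < Cg; ++c) {
    const double* xc = x + (size_t)(c0 + c) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = kh + KH * kw + KH * KW * c;
        for (int wo = 0; wo < WO; ++wo) {
          int wi = wo * sw - pw + kw;
          double* dst = col.colptr(0) + r; // stride over columns manually
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < HO; ++ho)
              col(r, ho + HO * wo) = 0.0;
            continue;
          }
          for (int ho = 0; ho < HO; ++ho) {
            int hi = ho * sh - ph + kh;
            col(r, ho + HO * wo) =
              (hi < 0 || hi >= H) ? 0.0 : xc[hi + H * wi];
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add a column matrix back into the (H, W) plane of channel group.
static void col2im(const arma::mat& col, int H, int W, int c0, int Cg,
                   int KH, int KW, int sh, int sw, int ph, int pw,
                   int HO, int WO, double* dx) {
  for (int c = 0; c < Cg; ++c) {
    double* xc = dx + (size_t)(c0 + c) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = kh + KH * kw + KH * KW * c;
        for (int wo = 0; wo < WO; ++wo) {
          int wi = wo * sw - pw + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < HO; ++ho) {
            int hi = ho * sh - ph + kh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + H * wi] += col(r, ho + HO * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        Nullable<NumericVector> bias,
                        int stride, int padh, int padw, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("conv2d: channel/group mismatch");
  int Og = Cout / groups;
  int HO = out_size(H, KH, stride, padh), WO = out_size(W, KW, stride, padw);
  if (HO < 1 || WO < 1) stop("conv2d: spatial size smaller than 1");
  NumericVector y((size_t)HO * WO * Cout * N);
  y.attr("dim") = IntegerVector::create(HO, WO, Cout, N);

  arma::mat col(KH * KW * Cg, HO * WO);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  bool has_b = bias.isNotNull();
  NumericVector b;
  if (has_b) b = bias.get();

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * C;
    double* yn = yp + (size_t)n * HO * WO * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, KH, KW, stride, stride, padh, padw, HO, WO, col);
      arma::mat Wg(const_cast<double*>(REAL(w)) + (size_t)g * Og * KH * KW * Cg,
                   KH * KW * Cg, Og, false, true);
      arma::mat out = Wg.t() * col; // (Og x HO*WO)
      for (int o = 0; o < Og; ++o) {
        double bo = has_b ? b[g * Og + o] : 0.0;
        double* yc = yn + (size_t)(g * Og + o) * HO * WO;
        const double* oc = out.memptr() + o; // row o, stride Og
        for (int i = 0; i < HO * WO; ++i) yc[i] = oc[(size_t)i * Og] + bo;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int padh, int padw, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  int HO = yd[0], WO = yd[1];
  int Og = Cout / groups;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)KH * KW * Cg * Cout);
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);

  arma::mat col(KH * KW * Cg, HO * WO);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * C;
    const double* dyn = dyp + (size_t)n * HO * WO * Cout;
    double* dxn = dxp + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      // dy for this group as (Og x HO*WO)
      arma::mat dyg(Og, HO * WO);
      for (int o = 0; o < Og; ++o) {
        const double* yc = dyn + (size_t)(g * Og + o) * HO * WO;
        for (int i = 0; i < HO * WO; ++i) dyg(o, i) = yc[i];
      }
      im2col(xn, H, W, g * Cg, Cg, KH, KW, stride, stride, padh, padw, HO, WO, col);
      // dW += col * dyg'
      arma::mat dWg = col * dyg.t(); // (KH*KW*Cg x Og)
      double* dwg = REAL(dw) + (size_t)g * Og * KH * KW * Cg;
      const double* src = dWg.memptr();
      for (size_t i = 0; i < (size_t)KH * KW * Cg * Og; ++i) dwg[i] += src[i];
      // dcol = W * dyg ; scatter to dx
      arma::mat Wg(const_cast<double*>(REAL(w)) + (size_t)g * Og * KH * KW * Cg,
                   KH * KW * Cg, Og, false, true);
      arma::mat dcol = Wg * dyg;
      col2im(dcol, H, W, g * Cg, Cg, KH, KW, stride, stride, padh, padw, HO, WO, dxn);
      if (has_bias)
        for (int o = 0; o < Og; ++o) db[g * Og + o] += arma::accu(dyg.row(o));
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = has_bias ? (SEXP)db : R_NilValue);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int HO = out_size(H, k, stride, pad), WO = out_size(W, k, stride, pad);
  NumericVector y((size_t)HO * WO * C * N);
  y.attr("dim") = IntegerVector::create(HO, WO, C, N);
  IntegerVector idx((size_t)HO * WO * C * N); // 1-based argmax into x plane
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * plane;
      size_t off = ((size_t)n * C + c) * HO * WO;
      for (int wo = 0; wo < WO; ++wo) {
        for (int ho = 0; ho < HO; ++ho) {
          double best = -INFINITY; int bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + H * wi];
              if (v > best) { best = v; bi = hi + H * wi; }
            }
          }
          yp[off + ho + HO * wo] = best;
          ip[off + ho + HO * wo] = bi + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx,
                         IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  int HO = yd[0], WO = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  double* dxp = REAL(dx);
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dxp + ((size_t)n * C + c) * plane;
      size_t off = ((size_t)n * C + c) * HO * WO;
      for (int i = 0; i < HO * WO; ++i)
        if (ip[off + i] > 0) dxc[ip[off + i] - 1] += dyp[off + i];
    }
  return dx;
}
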