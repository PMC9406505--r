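// Convolution and pooling kernels for the autodiff engine.
// Feature maps are R arrays with dim (H, W, C), column-major (H fastest).
// Weights are R arrays with dim (k, k, Cin, Cout); element [kh, kw, ci, co]
// multiplies input pixel (h*stride - pad + kh*dil, w*stride - pad + kw*dil).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

static arma::mat im2col(const double* x, int H, int W, int C,
                        int k, int stride, int pad, int dil,
                        int Ho, int Wo) {
  arma::mat col(Ho * Wo, (size_t)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        size_t colidx = (size_t)kh + (size_t)k * kw + (size_t)k * k * c;
        double* dst = col.colptr(colidx);
        if (stride == 1) {
          // contiguous run: hi = ho - pad + kh*dil, valid ho range known
          int off = kh * dil - pad;
          int ho0 = std::max(0, -off), ho1 = std::min(Ho, H - off);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            const double* src = xc + (size_t)H * wi + off;
            std::copy(src + ho0, src + ho1, dst + (size_t)Ho * wo + ho0);
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            const double* xcw = xc + (size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh * dil;
              if (hi < 0 || hi >= H) continue;
              dst[ho + (size_t)Ho * wo] = xcw[hi];
            }
          }
        }
      }
    }
  }
  return col;
}

// scatter-add a column-space gradient back onto the input image
static void col2im(const arma::mat& col, double* gx, int H, int W, int C,
                   int k, int stride, int pad, int dil, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        size_t colidx = (size_t)kh + (size_t)k * kw + (size_t)k * k * c;
        const double* src = col.colptr(colidx);
        if (stride == 1) {
          int off = kh * dil - pad;
          int ho0 = std::max(0, -off), ho1 = std::min(Ho, H - off);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            double* gcw = gc + (size_t)H * wi + off;
            const double* s = src + (size_t)Ho * wo;
            for (int ho = ho0; ho < ho1; ++ho) gcw[ho] += s[ho];
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            double* gcw = gc + (size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh * dil;
              if (hi < 0 || hi >= H) continue;
              gcw[hi] += src[ho + (size_t)Ho * wo];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = out_size(H, k, stride, pad, dil);
  int Wo = out_size(W, k, stride, pad, dil);
  if (Ho < 1 || Wo < 1)
    stop("conv2d: input %dx%d too small for kernel %d dilation %d", H, W, k, dil);
  arma::mat wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  if (k == 1 && stride == 1 && pad == 0) {
    // point-wise fast path: plain gemm on the (H*W, C) view
    arma::mat xm(const_cast<double*>(x.begin()), (size_t)H * W, C, false, true);
    arma::mat out = xm * wm;
    out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
    NumericVector res(out.begin(), out.end());
    res.attr("dim") = IntegerVector::create(H, W, Cout);
    return res;
  }
  arma::mat col = im2col(x.begin(), H, W, C, k, stride, pad, dil, Ho, Wo);
  arma::mat out = col * wm;
  out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  arma::mat gm(const_cast<double*>(gout.begin()), (size_t)Ho * Wo, Cout, false, true);
  arma::mat wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  if (k == 1 && stride == 1 && pad == 0) {
    arma::mat xm(const_cast<double*>(x.begin()), (size_t)H * W, C, false, true);
    arma::mat gw = xm.t() * gm;
    arma::rowvec gb = arma::sum(gm, 0);
    arma::mat gxm = gm * wm.t();
    NumericVector gx(gxm.begin(), gxm.end());
    gx.attr("dim") = xd;
    NumericVector gwv(gw.begin(), gw.end());
    gwv.attr("dim") = wd;
    NumericVector gbv(gb.begin(), gb.end());
    return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
  }
  arma::mat col = im2col(x.begin(), H, W, C, k, stride, pad, dil, Ho, Wo);

  arma::mat gw = col.t() * gm;
  arma::rowvec gb = arma::sum(gm, 0);
  arma::mat gcol = gm * wm.t();

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  col2im(gcol, gx.begin(), H, W, C, k, stride, pad, dil, Ho, Wo);

  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = wd;
  NumericVector gbv(gb.begin(), gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// [[Rcpp::export(name = ".maxpool2d_fwd")]]
List maxpool2d_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  NumericVector out((size_t)Ho * Wo * C);
  IntegerVector arg((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -INFINITY; int bidx = -1;
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            double v = xc[hi + (size_t)H * wi];
            if (v > best) { best = v; bidx = hi + H * wi; }
          }
        }
        size_t oi = (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * c;
        out[oi] = best;
        arg[oi] = bidx + H * W * c;  // flat index into x (0-based)
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2d_bwd")]]
NumericVector maxpool2d_bwd(NumericVector gout, IntegerVector argmax, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}
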