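// Dense numerical kernels for the feature-map operators.
//
// Array layout matches R's column-major rank-4 arrays with
// dim = c(H, W, C, B): element (h, w, c, b) sits at
// h + H*(w + W*(c + C*b)), all indices 0-based here.
// Convolutions are stride-1 with zero padding; weights have
// dim = c(k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx4(int h, int w, int c, int b, int H, int W, int C) {
  return (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * b));
}

static void im2col(const double* x, int H, int W, int C, int b,
                   int k, int pad, int dil, int Ho, int Wo, arma::mat& cols) {
  cols.zeros();
  for (int ci = 0; ci < C; ci++) {
    for (int kw = 0; kw < k; kw++) {
      for (int kh = 0; kh < k; kh++) {
        const int row = kh + k * (kw + k * ci);
        for (int wo = 0; wo < Wo; wo++) {
          const int wi = wo - pad + dil * kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ho++) {
            const int hi = ho - pad + dil * kh;
            if (hi < 0 || hi >= H) continue;
            cols(row, ho + (R_xlen_t)Ho * wo) = x[idx4(hi, wi, ci, b, H, W, C)];
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& wt, int k, int Cin, int Cout) {
  arma::mat Wm(Cout, (R_xlen_t)k * k * Cin);
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < Cin; ci++)
      for (int kw = 0; kw < k; kw++)
        for (int kh = 0; kh < k; kh++)
          Wm(co, kh + k * (kw + k * ci)) =
            wt[kh + (R_xlen_t)k * (kw + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector wt, NumericVector bias,
                            int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = H + 2 * pad - dil * (k - 1);
  const int Wo = W + 2 * pad - dil * (k - 1);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const bool has_bias = bias.size() > 0;
  NumericVector out((R_xlen_t)Ho * Wo * Cout * B);
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  if (k == 1 && pad == 0) {
    // pointwise conv: per-batch slice is already a contiguous (HW x C) matrix
    arma::mat Wm1(const_cast<double*>(wt.begin()), Cin, Cout, false, true);
    for (int b = 0; b < B; b++) {
      arma::mat X(const_cast<double*>(x.begin()) + (R_xlen_t)H * W * C * b,
                  (R_xlen_t)H * W, Cin, false, true);
      arma::mat O(out.begin() + HoWo * Cout * b, HoWo, Cout, false, true);
      O = X * Wm1;
      if (has_bias)
        for (int co = 0; co < Cout; co++) O.col(co) += bias[co];
    }
    out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
    return out;
  }
  arma::mat Wm = weight_matrix(wt, k, Cin, Cout);
  arma::mat cols((R_xlen_t)k * k * Cin, (R_xlen_t)Ho * Wo);
  for (int b = 0; b < B; b++) {
    im2col(x.begin(), H, W, C, b, k, pad, dil, Ho, Wo, cols);
    arma::mat outm = Wm * cols;  // Cout x HoWo
    for (int co = 0; co < Cout; co++) {
      const double bb = has_bias ? bias[co] : 0.0;
      double* op = out.begin() + HoWo * (co + (R_xlen_t)Cout * b);
      for (R_xlen_t j = 0; j < HoWo; j++) op[j] = outm(co, j) + bb;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector wt, NumericVector gout,
                   int pad, int dil, bool need_gx, bool need_gw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  IntegerVector gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  if (k == 1 && pad == 0) {
    arma::mat Wm1(const_cast<double*>(wt.begin()), Cin, Cout, false, true);
    NumericVector gx(need_gx ? x.size() : 0);
    arma::mat gWm1(Cin, Cout, arma::fill::zeros);
    NumericVector gb(Cout);
    for (int b = 0; b < B; b++) {
      arma::mat G(const_cast<double*>(gout.begin()) + HoWo * Cout * b,
                  HoWo, Cout, false, true);
      arma::mat X(const_cast<double*>(x.begin()) + (R_xlen_t)H * W * C * b,
                  (R_xlen_t)H * W, Cin, false, true);
      for (int co = 0; co < Cout; co++) gb[co] += arma::accu(G.col(co));
      if (need_gw) gWm1 += X.t() * G;
      if (need_gx) {
        arma::mat GX(gx.begin() + (R_xlen_t)H * W * C * b,
                     (R_xlen_t)H * W, Cin, false, true);
        GX = G * Wm1.t();
      }
    }
    NumericVector gw((R_xlen_t)Cin * Cout);
    if (need_gw) {
      std::copy(gWm1.begin(), gWm1.end(), gw.begin());
      gw.attr("dim") = IntegerVector::create(1, 1, Cin, Cout);
    }
    if (need_gx) gx.attr("dim") = xd;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat Wm = weight_matrix(wt, k, Cin, Cout);
  NumericVector gx(need_gx ? x.size() : 0);
  arma::mat gWm(Cout, (R_xlen_t)k * k * Cin, arma::fill::zeros);
  NumericVector gb(Cout);
  arma::mat cols((R_xlen_t)k * k * Cin, HoWo);
  arma::mat gom(Cout, HoWo);
  for (int b = 0; b < B; b++) {
    for (int co = 0; co < Cout; co++) {
      const double* gp = gout.begin() + HoWo * (co + (R_xlen_t)Cout * b);
      double s = 0.0;
      for (R_xlen_t j = 0; j < HoWo; j++) { gom(co, j) = gp[j]; s += gp[j]; }
      gb[co] += s;
    }
    if (need_gw) {
      im2col(x.begin(), H, W, C, b, k, pad, dil, Ho, Wo, cols);
      gWm += gom * cols.t();
    }
    if (need_gx) {
      arma::mat gcols = Wm.t() * gom;  // (k*k*Cin) x HoWo, scatter back (col2im)
      for (int ci = 0; ci < Cin; ci++) {
        for (int kw = 0; kw < k; kw++) {
          for (int kh = 0; kh < k; kh++) {
            const int row = kh + k * (kw + k * ci);
            for (int wo = 0; wo < Wo; wo++) {
              const int wi = wo - pad + dil * kw;
              if (wi < 0 || wi >= W) continue;
              for (int ho = 0; ho < Ho; ho++) {
                const int hi = ho - pad + dil * kh;
                if (hi < 0 || hi >= H) continue;
                gx[idx4(hi, wi, ci, b, H, W, C)] += gcols(row, ho + (R_xlen_t)Ho * wo);
              }
            }
          }
        }
      }
    }
  }
  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  if (need_gw) {
    for (int co = 0; co < Cout; co++)
      for (int ci = 0; ci < Cin; ci++)
        for (int kw = 0; kw < k; kw++)
          for (int kh = 0; kh < k; kh++)
            gw[kh + (R_xlen_t)k * (kw + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co))] =
              gWm(co, kh + k * (kw + k * ci));
    gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  }
  if (need_gx) gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++)
        for (int ho = 0; ho < Ho; ho++) {
          const int h = 2 * ho, w = 2 * wo;
          double s = x[idx4(h, w, c, b, H, W, C)] + x[idx4(h + 1, w, c, b, H, W, C)] +
                     x[idx4(h, w + 1, c, b, H, W, C)] + x[idx4(h + 1, w + 1, c, b, H, W, C)];
          out[idx4(ho, wo, c, b, Ho, Wo, C)] = 0.25 * s;
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector gout, int H, int W) {
  IntegerVector gd = gout.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], B = gd[3];
  NumericVector gx((R_xlen_t)H * W * C * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++)
        for (int ho = 0; ho < Ho; ho++) {
          const double g = 0.25 * gout[idx4(ho, wo, c, b, Ho, Wo, C)];
          const int h = 2 * ho, w = 2 * wo;
          gx[idx4(h, w, c, b, H, W, C)] += g;
          gx[idx4(h + 1, w, c, b, H, W, C)] += g;
          gx[idx4(h, w + 1, c, b, H, W, C)] += g;
          gx[idx4(h + 1, w + 1, c, b, H, W, C)] += g;
        }
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  return gx;
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  NumericVector idx((R_xlen_t)Ho * Wo * C * B);  // double to hold big offsets
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++)
        for (int ho = 0; ho < Ho; ho++) {
          const int h = 2 * ho, w = 2 * wo;
          R_xlen_t best = idx4(h, w, c, b, H, W, C);
          double bv = x[best];
          const R_xlen_t cand[3] = {idx4(h + 1, w, c, b, H, W, C),
                                    idx4(h, w + 1, c, b, H, W, C),
                                    idx4(h + 1, w + 1, c, b, H, W, C)};
          for (int q = 0; q < 3; q++)
            if (x[cand[q]] > bv) { bv = x[cand[q]]; best = cand[q]; }
          const R_xlen_t o = idx4(ho, wo, c, b, Ho, Wo, C);
          out[o] = bv;
          idx[o] = (double)best;
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gout, NumericVector idx,
                              int H, int W, int C, int B) {
  NumericVector gx((R_xlen_t)H * W * C * B);
  const R_xlen_t n = gout.size();
  for (R_xlen_t i = 0; i < n; i++) gx[(R_xlen_t)idx[i]] += gout[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  return gx;
}

// Bilinear interpolation, half-pixel centres (align_corners = FALSE).
static void bilin_coef(int n_in, int n_out, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& fr) {
  i0.resize(n_out); i1.resize(n_out); fr.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; i++) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int a = (int)std::floor(src);
    if (a > n_in - 1) a = n_in - 1;
    i0[i] = a;
    i1[i] = (a + 1 < n_in) ? a + 1 : a;
    fr[i] = src - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> fh, fw;
  bilin_coef(H, Ho, h0, h1, fh);
  bilin_coef(W, Wo, w0, w1, fw);
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++) {
      const double* xin = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
      double* oout = out.begin() + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * b);
      for (int wo = 0; wo < Wo; wo++) {
        const double* p0 = xin + (R_xlen_t)H * w0[wo];
        const double* p1 = xin + (R_xlen_t)H * w1[wo];
        double* po = oout + (R_xlen_t)Ho * wo;
        const double tw = fw[wo];
        for (int ho = 0; ho < Ho; ho++) {
          const double th = fh[ho];
          const double c0 = p0[h0[ho]] + th * (p0[h1[ho]] - p0[h0[ho]]);
          const double c1 = p1[h0[ho]] + th * (p1[h1[ho]] - p1[h0[ho]]);
          po[ho] = c0 + tw * (c1 - c0);
        }
      }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(NumericVector gout, int H, int W) {
  IntegerVector gd = gout.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], B = gd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> fh, fw;
  bilin_coef(H, Ho, h0, h1, fh);
  bilin_coef(W, Wo, w0, w1, fw);
  NumericVector gx((R_xlen_t)H * W * C * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++)
        for (int ho = 0; ho < Ho; ho++) {
          const double g = gout[idx4(ho, wo, c, b, Ho, Wo, C)];
          const double th = fh[ho], tw = fw[wo];
          gx[idx4(h0[ho], w0[wo], c, b, H, W, C)] += (1 - th) * (1 - tw) * g;
          gx[idx4(h1[ho], w0[wo], c, b, H, W, C)] += th * (1 - tw) * g;
          gx[idx4(h0[ho], w1[wo], c, b, H, W, C)] += (1 - th) * tw * g;
          gx[idx4(h1[ho], w1[wo], c, b, H, W, C)] += th * tw * g;
        }
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  return gx;
}
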