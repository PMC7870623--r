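// Low-level numerical kernels for the small convolutional-network engine.
//
// Tensor layout convention (shared with the R layer code): a batch of
// feature maps is a 4D array with dim = c(H, W, N, C) — rows, columns,
// batch index, channel.  Convolution weights are c(k, k, Cin, Cout).
// All convolutions are stride 1 with "same" zero padding of (k-1)/2;
// the transposed convolution is fixed at kernel 2x2, stride 2 (so output
// blocks do not overlap and both passes are cheap and exact).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(int h, int w, int n, int c,
                               int H, int W, int N) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w +
         (arma::uword)W * ((arma::uword)n + (arma::uword)N * (arma::uword)c));
}

static void get_dims(const NumericVector& x, int* d, int nd) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != nd) stop("expected a %d-d array", nd);
  for (int i = 0; i < nd; ++i) d[i] = dim[i];
}

// im2col (transposed layout) for one image: colsT is (H*W) x (k*k*Cin),
// so the inner (ho) loop writes contiguous memory.
static void im2col_one(const double* x, int n, int H, int W, int N, int Cin,
                       int k, int pad, arma::mat& colsT) {
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int r = ki + k * (kj + k * ci);
        double* dst0 = colsT.memptr() + (arma::uword)(H * W) * r;
        int ho_lo = std::max(0, pad - ki);
        int ho_hi = std::min(H - 1, H - 1 + pad - ki);
        for (int wo = 0; wo < W; ++wo) {
          int wi = wo + kj - pad;
          double* dst = dst0 + (arma::uword)H * wo;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = x + idx4(0, wi, n, ci, H, W, N) + (ki - pad);
          for (int ho = 0; ho < ho_lo; ++ho) dst[ho] = 0.0;
          for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] = src[ho];
          for (int ho = ho_hi + 1; ho < H; ++ho) dst[ho] = 0.0;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims(x, dx, 4); get_dims(w, dw, 4);
  int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("weight dims do not match input channels");
  int pad = (k - 1) / 2;

  // WmT: (k*k*Cin) x Cout; weight memory is already in that order
  const arma::mat WmT(const_cast<double*>(w.begin()),
                      (arma::uword)(k * k * Cin), (arma::uword)Cout,
                      false, true);

  NumericVector y((R_xlen_t)H * W * N * Cout);
  y.attr("dim") = IntegerVector::create(H, W, N, Cout);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* bp = b.begin();

  arma::mat colsT((arma::uword)(H * W), (arma::uword)(k * k * Cin));
  for (int n = 0; n < N; ++n) {
    im2col_one(xp, n, H, W, N, Cin, k, pad, colsT);
    arma::mat out = colsT * WmT;         // (H*W) x Cout
    for (int co = 0; co < Cout; ++co) {
      double bb = bp[co];
      double* ybase = yp + idx4(0, 0, n, co, H, W, N);
      const double* ocol = out.colptr(co);
      for (int p = 0; p < H * W; ++p) ybase[p] = ocol[p] + bb;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  get_dims(x, dx_, 4); get_dims(w, dw_, 4);
  int H = dx_[0], W = dx_[1], N = dx_[2], Cin = dx_[3];
  int k = dw_[0], Cout = dw_[3];
  int pad = (k - 1) / 2;

  const arma::mat WmT(const_cast<double*>(w.begin()),
                      (arma::uword)(k * k * Cin), (arma::uword)Cout,
                      false, true);

  NumericVector dxv((R_xlen_t)H * W * N * Cin);
  dxv.attr("dim") = IntegerVector::create(H, W, N, Cin);
  NumericVector dwv((R_xlen_t)k * k * Cin * Cout);
  dwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector dbv(Cout);

  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dxv.begin();

  // dW accumulator aliases the output array (same (k*k*Cin) x Cout order)
  arma::mat dWT(dwv.begin(), (arma::uword)(k * k * Cin), (arma::uword)Cout,
                false, true);
  arma::vec dB((arma::uword)Cout, arma::fill::zeros);
  arma::mat colsT((arma::uword)(H * W), (arma::uword)(k * k * Cin));
  arma::mat dYmT((arma::uword)(H * W), (arma::uword)Cout);

  for (int n = 0; n < N; ++n) {
    im2col_one(xp, n, H, W, N, Cin, k, pad, colsT);
    for (int co = 0; co < Cout; ++co) {
      const double* dybase = dyp + idx4(0, 0, n, co, H, W, N);
      std::copy(dybase, dybase + H * W, dYmT.colptr(co));
    }
    dWT += colsT.t() * dYmT;
    dB += arma::sum(dYmT, 0).t();
    arma::mat dcolsT = dYmT * WmT.t();   // (H*W) x (k*k*Cin)
    // col2im: scatter-add
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          int r = ki + k * (kj + k * ci);
          const double* src0 = dcolsT.colptr(r);
          int ho_lo = std::max(0, pad - ki);
          int ho_hi = std::min(H - 1, H - 1 + pad - ki);
          for (int wo = 0; wo < W; ++wo) {
            int wi = wo + kj - pad;
            if (wi < 0 || wi >= W) continue;
            double* dst = dxp + idx4(0, wi, n, ci, H, W, N) + (ki - pad);
            const double* src = src0 + (arma::uword)H * wo;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] += src[ho];
          }
        }
  }

  for (int co = 0; co < Cout; ++co) dbv[co] = dB(co);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max-pooling, stride 2.  Returns pooled maps and the flat index (1-based,
// into the input array) of each winning element for the backward pass.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  int d[4]; get_dims(x, d, 4);
  int H = d[0], W = d[1], N = d[2], C = d[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * N * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  IntegerVector amax((R_xlen_t)Ho * Wo * N * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = amax.begin();
  R_xlen_t q = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; arma::uword bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              arma::uword ii = idx4(2 * ho + di, 2 * wo + dj, n, c, H, W, N);
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          arma::uword oi = idx4(ho, wo, n, c, Ho, Wo, N);
          yp[oi] = best; ap[oi] = (int)(bi + 1);
          ++q;
        }
  (void)q;
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(IntegerVector argmax, NumericVector dy,
                               IntegerVector in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = argmax.begin();
  R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ap[i] - 1] += dyp[i];
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (exact upsampling by 2).
// w: 2 x 2 x Cin x Cout
// [[Rcpp::export(name = ".cpp_convt2_fwd")]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx_[4], dw_[4];
  get_dims(x, dx_, 4); get_dims(w, dw_, 4);
  int H = dx_[0], W = dx_[1], N = dx_[2], Cin = dx_[3];
  int Cout = dw_[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * N * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bb = b[co];
    for (int n = 0; n < N; ++n)
      for (int wj = 0; wj < W; ++wj)
        for (int hi = 0; hi < H; ++hi) {
          double acc00 = bb * 0, acc10 = 0, acc01 = 0, acc11 = 0;
          for (int ci = 0; ci < Cin; ++ci) {
            double xv = xp[idx4(hi, wj, n, ci, H, W, N)];
            const double* wbase = wp + 4 * ((arma::uword)ci + Cin * (arma::uword)co);
            acc00 += xv * wbase[0];
            acc10 += xv * wbase[1];
            acc01 += xv * wbase[2];
            acc11 += xv * wbase[3];
          }
          yp[idx4(2 * hi,     2 * wj,     n, co, Ho, Wo, N)] = acc00 + bb;
          yp[idx4(2 * hi + 1, 2 * wj,     n, co, Ho, Wo, N)] = acc10 + bb;
          yp[idx4(2 * hi,     2 * wj + 1, n, co, Ho, Wo, N)] = acc01 + bb;
          yp[idx4(2 * hi + 1, 2 * wj + 1, n, co, Ho, Wo, N)] = acc11 + bb;
        }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_convt2_bwd")]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  get_dims(x, dx_, 4); get_dims(w, dw_, 4);
  int H = dx_[0], W = dx_[1], N = dx_[2], Cin = dx_[3];
  int Cout = dw_[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dxv((R_xlen_t)H * W * N * Cin);
  dxv.attr("dim") = IntegerVector::create(H, W, N, Cin);
  NumericVector dwv((R_xlen_t)4 * Cin * Cout);
  dwv.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  NumericVector dbv(Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dxv.begin(); double* dwp = dwv.begin();
  for (int co = 0; co < Cout; ++co) {
    double db = 0;
    for (int n = 0; n < N; ++n)
      for (int wj = 0; wj < W; ++wj)
        for (int hi = 0; hi < H; ++hi) {
          double g00 = dyp[idx4(2 * hi,     2 * wj,     n, co, Ho, Wo, N)];
          double g10 = dyp[idx4(2 * hi + 1, 2 * wj,     n, co, Ho, Wo, N)];
          double g01 = dyp[idx4(2 * hi,     2 * wj + 1, n, co, Ho, Wo, N)];
          double g11 = dyp[idx4(2 * hi + 1, 2 * wj + 1, n, co, Ho, Wo, N)];
          db += g00 + g10 + g01 + g11;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* wbase = wp + 4 * ((arma::uword)ci + Cin * (arma::uword)co);
            double* dwbase = dwp + 4 * ((arma::uword)ci + Cin * (arma::uword)co);
            double xv = xp[idx4(hi, wj, n, ci, H, W, N)];
            dxp[idx4(hi, wj, n, ci, H, W, N)] +=
              g00 * wbase[0] + g10 * wbase[1] + g01 * wbase[2] + g11 * wbase[3];
            dwbase[0] += g00 * xv; dwbase[1] += g10 * xv;
            dwbase[2] += g01 * xv; dwbase[3] += g11 * xv;
          }
        }
    dbv[co] = db;
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Zero-normalized cross-correlation map over all full-overlap placements.
// image: R x C matrix; patch: r x c matrix.  Result (R-r+1) x (C-c+1);
// entry (i, j) is the ZNCC of the patch with the window whose top-left is
// (i, j).  Windows with zero variance score 0.
// [[Rcpp::export(name = ".cpp_zncc_map")]]
NumericMatrix cpp_zncc_map(NumericMatrix image, NumericMatrix patch) {
  int R = image.nrow(), C = image.ncol();
  int pr = patch.nrow(), pc = patch.ncol();
  if (pr > R || pc > C) stop("patch larger than image");
  int orows = R - pr + 1, ocols = C - pc + 1;
  double pmean = 0;
  for (int j = 0; j < pc; ++j) for (int i = 0; i < pr; ++i) pmean += patch(i, j);
  pmean /= (double)(pr * pc);
  arma::mat P0(pr, pc);
  double pss = 0;
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i) { P0(i, j) = patch(i, j) - pmean; pss += P0(i, j) * P0(i, j); }
  if (pss <= 0) stop("patch has zero variance");
  double pden = std::sqrt(pss);

  // integral images of I and I^2 (with leading zero row/col)
  arma::mat S1(R + 1, C + 1, arma::fill::zeros), S2(R + 1, C + 1, arma::fill::zeros);
  for (int j = 1; j <= C; ++j)
    for (int i = 1; i <= R; ++i) {
      double v = image(i - 1, j - 1);
      S1(i, j) = v + S1(i - 1, j) + S1(i, j - 1) - S1(i - 1, j - 1);
      S2(i, j) = v * v + S2(i - 1, j) + S2(i, j - 1) - S2(i - 1, j - 1);
    }

  NumericMatrix out(orows, ocols);
  double npix = (double)(pr * pc);
  for (int j = 0; j < ocols; ++j)
    for (int i = 0; i < orows; ++i) {
      double cross = 0;
      for (int q = 0; q < pc; ++q)
        for (int p = 0; p < pr; ++p)
          cross += image(i + p, j + q) * P0(p, q);
      double s1 = S1(i + pr, j + pc) - S1(i, j + pc) - S1(i + pr, j) + S1(i, j);
      double s2 = S2(i + pr, j + pc) - S2(i, j + pc) - S2(i + pr, j) + S2(i, j);
      double wss = s2 - s1 * s1 / npix;
      out(i, j) = (wss <= 1e-12) ? 0.0 : cross / (std::sqrt(wss) * pden);
    }
  return out;
}

// ---- elementwise / per-channel helpers (channel = slowest dim) ----------

// [[Rcpp::export(name = ".cpp_elu_fwd")]]
NumericVector cpp_elu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : std::expm1(xp[i]);
  return y;
}

// [[Rcpp::export(name = ".cpp_elu_bwd")]]
NumericVector cpp_elu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* yp = y.begin(); const double* dp = dy.begin();
  double* op = dx.begin();
  R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i)
    op[i] = yp[i] > 0 ? dp[i] : dp[i] * (yp[i] + 1.0);
  return dx;
}

// batch-norm forward over an (H, W, N, C) array: per-channel moments,
// normalized output and y = gamma * xhat + beta in one pass.
// Returns list(y, xhat, mu, var).
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta) {
  int d[4]; get_dims(x, d, 4);
  R_xlen_t m = (R_xlen_t)d[0] * d[1] * d[2];
  int C = d[3];
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim"); xhat.attr("dim") = x.attr("dim");
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  double* yp = y.begin(); double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + m * c;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < m; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    double mn = s / m;
    double v = s2 / m - mn * mn;
    if (v < 0) v = 0;
    mu[c] = mn; var[c] = v;
    double inv = 1.0 / std::sqrt(v + 1e-5);
    double g = gamma[c], b = beta[c];
    double* yc = yp + m * c; double* hc = hp + m * c;
    for (R_xlen_t i = 0; i < m; ++i) {
      double h = (xc[i] - mn) * inv;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var);
}

// batch-norm inference using running moments
// [[Rcpp::export(name = ".cpp_bn_eval")]]
NumericVector cpp_bn_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector rm,
                          NumericVector rv) {
  int d[4]; get_dims(x, d, 4);
  R_xlen_t m = (R_xlen_t)d[0] * d[1] * d[2];
  int C = d[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(rv[c] + 1e-5);
    double g = gamma[c], b = beta[c], mn = rm[c];
    const double* xc = xp + m * c; double* yc = yp + m * c;
    for (R_xlen_t i = 0; i < m; ++i) yc[i] = g * (xc[i] - mn) * inv + b;
  }
  return y;
}

// batch-norm backward; var is the batch variance from the forward pass.
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector xhat, NumericVector dy, NumericVector gamma,
                NumericVector var) {
  int d[4]; get_dims(xhat, d, 4);
  R_xlen_t m = (R_xlen_t)d[0] * d[1] * d[2];
  int C = d[3];
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const double* hp = xhat.begin(); const double* dp = dy.begin();
  double* op = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* hc = hp + m * c; const double* dc = dp + m * c;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < m; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    double inv = 1.0 / std::sqrt(var[c] + 1e-5);
    double g = gamma[c];
    double a = g * inv, t1 = sb / m, t2 = sg / m;
    double* oc = op + m * c;
    for (R_xlen_t i = 0; i < m; ++i)
      oc[i] = a * (dc[i] - t1 - hc[i] * t2);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// multiply each (n, c) feature map by mask(n, c) (channel dropout)
// [[Rcpp::export(name = ".cpp_scale_nc")]]
NumericVector cpp_scale_nc(NumericVector x, NumericMatrix mask) {
  int d[4]; get_dims(x, d, 4);
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  int N = d[2], C = d[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double s = mask(n, c);
      const double* xc = xp + hw * (n + (R_xlen_t)N * c);
      double* yc = yp + hw * (n + (R_xlen_t)N * c);
      if (s == 0) std::fill(yc, yc + hw, 0.0);
      else for (R_xlen_t i = 0; i < hw; ++i) yc[i] = s * xc[i];
    }
  return y;
}
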