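// Low-level tensor kernels for the segmentation networks.
//
// Tensor convention throughout: R numeric arrays with dim (H, W, C, B),
// column-major, so element (h, w, c, b) sits at h + H*(w + W*(c + C*b)).
// Convolutions are realized as im2col + GEMM (Armadillo dgemm); backward
// passes rebuild the column matrix instead of caching it, trading ~30%
// extra FLOPs for a much smaller memory footprint.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// C (M x N, ldc) <- alpha * op(A) op(B) + beta * C, thin dgemm wrapper so
// products can accumulate straight into strided submatrix views without
// temporaries.
static void gemm_acc(char ta, char tb, int M, int N, int K, double alpha,
                     const double* A, int lda, const double* B, int ldb,
                     double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &M, &N, &K, &alpha, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, C, &ldc
                  FCONE FCONE);
}

static inline arma::uvec get_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  arma::uvec out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = d[i];
  return out;
}

// Fill the row-major-patch im2col matrix for one sample:
// Arow is (Ho*Wo) x (Cin*k*k) with row q = ho + Ho*wo and column
// r = ki + k*(kj + k*cin). Patch rows as GEMM M keeps every product
// tall-skinny, which BLAS handles far better than a tiny-M layout.
static void im2row(const double* xs, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& Arow) {
  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = xs + (size_t)cin * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* acol = Arow.colptr(ki + k * (kj + k * cin));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* aq = acol + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::memset(aq, 0, sizeof(double) * Ho);
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          const int hi0 = -pad + ki;
          if (stride == 1) {
            // contiguous copy of the valid range, zero the pad fringes
            int lo = std::max(0, -hi0);
            int hiend = std::min(Ho, H - hi0);
            if (lo > 0) std::memset(aq, 0, sizeof(double) * lo);
            if (lo < hiend)
              std::memcpy(aq + lo, xcol + hi0 + lo, sizeof(double) * (hiend - lo));
            if (hiend < Ho) std::memset(aq + hiend, 0, sizeof(double) * (Ho - hiend));
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + hi0;
            aq[ho] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add the patch-row matrix back onto the input grid (adjoint).
static void row2im_add(const arma::mat& Grow, int H, int W, int Cin,
                       int k, int stride, int pad, int Ho, int Wo,
                       double* gxs) {
  for (int cin = 0; cin < Cin; ++cin) {
    double* gc = gxs + (size_t)cin * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* acol = Grow.colptr(ki + k * (kj + k * cin));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)wi * H;
          const double* aq = acol + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            gcol[hi] += aq[ho];
          }
        }
      }
    }
  }
}

// Weights as a (Cin*k*k) x Cout matrix; its memory layout already matches
// the (k, k, Cin, Cout) R array, so wrap without copying.
static arma::mat weight_matrix_t(const NumericVector& w, int k, int Cin, int Cout) {
  return arma::mat(const_cast<double*>(w.begin()),
                   (size_t)k * k * Cin, Cout, false, true);
}

// ---- 3x3 stride-1 pad-1 fast path ------------------------------------------
// Direct convolution as nine shifted GEMMs on submatrix views of the input,
// so no inflated patch matrix is ever materialized and the operands stay
// cache-resident. A shift by (di, dj) is the flat offset s = di + H*dj on
// the (H*W) x Cin sample matrix; rows that would wrap across a column
// boundary (di != 0) receive a wrong neighbor and are fixed by a small
// correction GEMM over the affected rows (one per image column).

// Extract the (Cin x Cout) weight slice for kernel tap (ki, kj) from the
// (9*Cin) x Cout matrix whose rows are ki + 3*kj + 9*cin.
static arma::mat tap_weights(const arma::mat& WmT, int ki, int kj, int Cin) {
  arma::mat Wq(Cin, WmT.n_cols);
  for (int cin = 0; cin < Cin; ++cin)
    Wq.row(cin) = WmT.row(ki + 3 * kj + 9 * cin);
  return Wq;
}

// Rows of Y wrongly updated by shift (di, dj): output rows q = rh + H*wo,
// reading input row q + s (in-bounds but in the adjacent column). Returns
// the list of (q, q + s) pairs.
static void wrap_rows(int di, int dj, int H, int W, long q0, long q1,
                      std::vector<long>& qs, std::vector<long>& ps) {
  qs.clear(); ps.clear();
  if (di == 0) return;
  const int rh = di == 1 ? H - 1 : 0;
  const long s = di + (long)H * dj;
  for (int wo = 0; wo < W; ++wo) {
    const long q = rh + (long)H * wo;
    if (q < q0 || q >= q1) continue;
    qs.push_back(q);
    ps.push_back(q + s);
  }
}

static void conv3_fwd_sample(const double* xs, const arma::mat& WmT,
                             const NumericVector& bias,
                             int H, int W, int Cin, int Cout, double* ys) {
  const long HW = (long)H * W;
  arma::mat Xs(const_cast<double*>(xs), HW, Cin, false, true);
  arma::mat Ys(ys, HW, Cout, false, true);
  for (int co = 0; co < Cout; ++co) Ys.col(co).fill(bias[co]);
  std::vector<long> qs, ps;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const long s = di + (long)H * dj;
      const long q0 = std::max(0L, -s), q1 = HW - std::max(0L, s);
      if (q0 >= q1) continue;
      arma::mat Wq = tap_weights(WmT, di + 1, dj + 1, Cin);
      gemm_acc('N', 'N', (int)(q1 - q0), Cout, Cin, 1.0,
               xs + (q0 + s), (int)HW, Wq.memptr(), Cin,
               1.0, ys + q0, (int)HW);
      wrap_rows(di, dj, H, W, q0, q1, qs, ps);
      if (!qs.empty()) {
        arma::mat Xc(qs.size(), Cin);
        for (size_t t = 0; t < ps.size(); ++t) Xc.row(t) = Xs.row(ps[t]);
        arma::mat Cor = Xc * Wq;
        for (size_t t = 0; t < qs.size(); ++t) Ys.row(qs[t]) -= Cor.row(t);
      }
    }
  }
}

static void conv3_bwd_sample(const double* xs, const double* gys,
                             const arma::mat& WmT, int H, int W,
                             int Cin, int Cout,
                             double* gxs, arma::mat& GWt, arma::vec& gb) {
  const long HW = (long)H * W;
  arma::mat Xs(const_cast<double*>(xs), HW, Cin, false, true);
  arma::mat Gys(const_cast<double*>(gys), HW, Cout, false, true);
  arma::mat GXs(gxs, HW, Cin, false, true);
  gb += arma::sum(Gys, 0).t();
  std::vector<long> qs, ps;
  arma::mat GWq(Cin, Cout);
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const long s = di + (long)H * dj;
      const long q0 = std::max(0L, -s), q1 = HW - std::max(0L, s);
      if (q0 >= q1) continue;
      arma::mat Wq = tap_weights(WmT, di + 1, dj + 1, Cin);
      const int len = (int)(q1 - q0);
      // forward was Y[q] += X[q+s] Wq  =>
      //   dX[q+s] += dY[q] Wq^T ;  dWq += X[q+s]^T dY[q]
      gemm_acc('N', 'T', len, Cin, Cout, 1.0,
               gys + q0, (int)HW, Wq.memptr(), Cin,
               1.0, gxs + (q0 + s), (int)HW);
      gemm_acc('T', 'N', Cin, Cout, len, 1.0,
               xs + (q0 + s), (int)HW, gys + q0, (int)HW,
               0.0, GWq.memptr(), Cin);
      wrap_rows(di, dj, H, W, q0, q1, qs, ps);
      if (!qs.empty()) {
        arma::mat Gc(qs.size(), Cout), Xc(ps.size(), Cin);
        for (size_t t = 0; t < qs.size(); ++t) {
          Gc.row(t) = Gys.row(qs[t]);
          Xc.row(t) = Xs.row(ps[t]);
        }
        arma::mat CorX = Gc * Wq.t();
        for (size_t t = 0; t < ps.size(); ++t) GXs.row(ps[t]) -= CorX.row(t);
        GWq -= Xc.t() * Gc;
      }
      for (int cin = 0; cin < Cin; ++cin)
        GWt.row((di + 1) + 3 * (dj + 1) + 9 * cin) += GWq.row(cin);
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  arma::uvec xd = get_dims(x), wd = get_dims(w);
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  if ((int)wd[2] != Cin) stop("conv2d_fwd: input has %d channels but kernel expects %d", Cin, (int)wd[2]);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d_fwd: output size would be empty");

  arma::mat WmT = weight_matrix_t(w, k, Cin, Cout);
  NumericVector y((size_t)Ho * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);

  if (k == 1 && stride == 1 && pad == 0) {
    // pointwise conv: plain GEMM per sample, no patch matrix
    for (int b = 0; b < B; ++b) {
      arma::mat Xb(const_cast<double*>(x.begin()) + (size_t)b * H * W * Cin,
                   (size_t)H * W, Cin, false, true);
      arma::mat Yb(y.begin() + (size_t)b * H * W * Cout, (size_t)H * W, Cout, false, true);
      Yb = Xb * WmT;
      for (int co = 0; co < Cout; ++co) Yb.col(co) += bias[co];
    }
    return y;
  }

  if (k == 3 && stride == 1 && pad == 1 && W >= 2) {
    for (int b = 0; b < B; ++b) {
      conv3_fwd_sample(x.begin() + (size_t)b * H * W * Cin, WmT, bias,
                       H, W, Cin, Cout, y.begin() + (size_t)b * H * W * Cout);
    }
    return y;
  }

  arma::mat Arow((size_t)Ho * Wo, (size_t)Cin * k * k);
  for (int b = 0; b < B; ++b) {
    const double* xs = x.begin() + (size_t)b * H * W * Cin;
    im2row(xs, H, W, Cin, k, stride, pad, Ho, Wo, Arow);
    double* ys = y.begin() + (size_t)b * Ho * Wo * Cout;
    // (Ho*Wo) x Cout output written straight into the R array
    arma::mat Yt(ys, (size_t)Ho * Wo, Cout, false, true);
    Yt = Arow * WmT;
    for (int co = 0; co < Cout; ++co) {
      double* yc = ys + (size_t)co * Ho * Wo;
      const double bv = bias[co];
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) yc[q] += bv;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  arma::uvec xd = get_dims(x), wd = get_dims(w), gd = get_dims(gy);
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  arma::mat WmT = weight_matrix_t(w, k, Cin, Cout);
  arma::mat GWt((size_t)Cin * k * k, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");

  if (k == 1 && stride == 1 && pad == 0) {
    for (int b = 0; b < B; ++b) {
      arma::mat Xb(const_cast<double*>(x.begin()) + (size_t)b * H * W * Cin,
                   (size_t)H * W, Cin, false, true);
      arma::mat Gb(const_cast<double*>(gy.begin()) + (size_t)b * Ho * Wo * Cout,
                   (size_t)Ho * Wo, Cout, false, true);
      arma::mat GXb(gx.begin() + (size_t)b * H * W * Cin, (size_t)H * W, Cin, false, true);
      GXb = Gb * WmT.t();
      GWt += Xb.t() * Gb;
      gb += arma::sum(Gb, 0).t();
    }
    NumericVector gw1(w.size());
    gw1.attr("dim") = w.attr("dim");
    std::memcpy(gw1.begin(), GWt.memptr(), sizeof(double) * GWt.n_elem);
    return List::create(_["gx"] = gx, _["gw"] = gw1,
                        _["gb"] = NumericVector(gb.begin(), gb.end()));
  }

  if (k == 3 && stride == 1 && pad == 1 && W >= 2) {
    for (int b = 0; b < B; ++b) {
      conv3_bwd_sample(x.begin() + (size_t)b * H * W * Cin,
                       gy.begin() + (size_t)b * H * W * Cout,
                       WmT, H, W, Cin, Cout,
                       gx.begin() + (size_t)b * H * W * Cin, GWt, gb);
    }
    NumericVector gw3(w.size());
    gw3.attr("dim") = w.attr("dim");
    std::memcpy(gw3.begin(), GWt.memptr(), sizeof(double) * GWt.n_elem);
    return List::create(_["gx"] = gx, _["gw"] = gw3,
                        _["gb"] = NumericVector(gb.begin(), gb.end()));
  }

  arma::mat Arow((size_t)Ho * Wo, (size_t)Cin * k * k);
  for (int b = 0; b < B; ++b) {
    const double* xs = x.begin() + (size_t)b * H * W * Cin;
    const double* gs = gy.begin() + (size_t)b * Ho * Wo * Cout;
    // gy sample as (Ho*Wo) x Cout col-major view, no copy
    arma::mat Gys(const_cast<double*>(gs), (size_t)Ho * Wo, Cout, false, true);
    im2row(xs, H, W, Cin, k, stride, pad, Ho, Wo, Arow);
    GWt += Arow.t() * Gys;
    gb += arma::sum(Gys, 0).t();
    arma::mat Grow = Gys * WmT.t();          // (Ho*Wo) x (Cin*k*k)
    row2im_add(Grow, H, W, Cin, k, stride, pad, Ho, Wo,
               gx.begin() + (size_t)b * H * W * Cin);
  }

  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  std::memcpy(gw.begin(), GWt.memptr(), sizeof(double) * GWt.n_elem);

  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  arma::uvec xd = get_dims(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) stop("maxpool2_fwd: spatial size %dx%d not divisible by 2", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx(y.size()); // absolute linear index into x of the argmax

  const double* xp = x.begin();
  double* yp = y.begin();
  size_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)c + (size_t)C * b) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = base + (size_t)(2 * wo) * H + 2 * ho;
          size_t cand[4] = {i00, i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          size_t best = cand[0];
          for (int t = 1; t < 4; ++t) if (xp[cand[t]] > xp[best]) best = cand[t];
          // output layout loops: ho fastest, but o increments per (wo,ho);
          // recompute target index explicitly to stay layout-correct
          size_t oi = ((size_t)c + (size_t)C * b) * Ho * Wo + (size_t)wo * Ho + ho;
          yp[oi] = xp[best];
          idx[oi] = (int)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Bilinear 2x upsampling, align_corners = FALSE convention:
// source coordinate of output d is (d + 0.5)/2 - 0.5.
static void up2_coeffs(int Ho, int H, std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<double>& f1) {
  i0.resize(Ho); i1.resize(Ho); f1.resize(Ho);
  for (int d = 0; d < Ho; ++d) {
    double s = (d + 0.5) / 2.0 - 0.5;
    int a = (int)std::floor(s);
    double f = s - a;
    int b = a + 1;
    if (a < 0) { a = 0; }
    if (b > H - 1) { b = H - 1; }
    if (a > H - 1) a = H - 1;
    i0[d] = a; i1[d] = b; f1[d] = f;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  arma::uvec xd = get_dims(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> rf, cf;
  up2_coeffs(Ho, H, r0, r1, rf);
  up2_coeffs(Wo, W, c0, c1, cf);
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)c + (size_t)C * b) * H * W;
      double* ys = yp + ((size_t)c + (size_t)C * b) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* xa = xs + (size_t)c0[wo] * H;
        const double* xb = xs + (size_t)c1[wo] * H;
        const double wc1 = cf[wo], wc0 = 1.0 - wc1;
        double* yc = ys + (size_t)wo * Ho;
        for (int ho = 0; ho < Ho; ++ho) {
          const double wr1 = rf[ho], wr0 = 1.0 - wr1;
          yc[ho] = wr0 * (wc0 * xa[r0[ho]] + wc1 * xb[r0[ho]]) +
                   wr1 * (wc0 * xa[r1[ho]] + wc1 * xb[r1[ho]]);
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> rf, cf;
  up2_coeffs(Ho, H, r0, r1, rf);
  up2_coeffs(Wo, W, c0, c1, cf);
  NumericVector gx((size_t)H * W * C * B);
  gx.attr("dim") = xdim;
  const double* gp = gy.begin(); double* xp = gx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* xs = xp + ((size_t)c + (size_t)C * b) * H * W;
      const double* gs = gp + ((size_t)c + (size_t)C * b) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        double* xa = xs + (size_t)c0[wo] * H;
        double* xb = xs + (size_t)c1[wo] * H;
        const double wc1 = cf[wo], wc0 = 1.0 - wc1;
        const double* gc = gs + (size_t)wo * Ho;
        for (int ho = 0; ho < Ho; ++ho) {
          const double wr1 = rf[ho], wr0 = 1.0 - wr1, g = gc[ho];
          xa[r0[ho]] += wr0 * wc0 * g;
          xb[r0[ho]] += wr0 * wc1 * g;
          xa[r1[ho]] += wr1 * wc0 * g;
          xb[r1[ho]] += wr1 * wc1 * g;
        }
      }
    }
  return gx;
}

// Batch norm over (H, W, B) per channel, training statistics (biased var).
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  arma::uvec xd = get_dims(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  const double N = (double)plane * B;
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* xs = x.begin() + ((size_t)c + (size_t)C * b) * plane;
      for (size_t i = 0; i < plane; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    const double m = s / N;
    const double v = s2 / N - m * m;
    mean[c] = m; var[c] = v > 0 ? v : 0;
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], bb = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xs = x.begin() + ((size_t)c + (size_t)C * b) * plane;
      double* ys = y.begin() + ((size_t)c + (size_t)C * b) * plane;
      for (size_t i = 0; i < plane; ++i) ys[i] = g * (xs[i] - m) * inv + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
            NumericVector var, double eps, NumericVector gy) {
  arma::uvec xd = get_dims(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t plane = (size_t)H * W;
  const double N = (double)plane * B;
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], inv = 1.0 / std::sqrt(var[c] + eps), g = gamma[c];
    double sg = 0, sgx = 0;
    for (int b = 0; b < B; ++b) {
      const double* xs = x.begin() + ((size_t)c + (size_t)C * b) * plane;
      const double* gs = gy.begin() + ((size_t)c + (size_t)C * b) * plane;
      for (size_t i = 0; i < plane; ++i) {
        sg += gs[i];
        sgx += gs[i] * (xs[i] - m) * inv;
      }
    }
    gbeta[c] = sg; ggamma[c] = sgx;
    const double mg = sg / N, mgx = sgx / N;
    for (int b = 0; b < B; ++b) {
      const double* xs = x.begin() + ((size_t)c + (size_t)C * b) * plane;
      const double* gs = gy.begin() + ((size_t)c + (size_t)C * b) * plane;
      double* os = gx.begin() + ((size_t)c + (size_t)C * b) * plane;
      for (size_t i = 0; i < plane; ++i) {
        const double xh = (xs[i] - m) * inv;
        os[i] = g * inv * (gs[i] - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector bn_eval(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector rmean, NumericVector rvar, double eps) {
  arma::uvec xd = get_dims(x);
  const int C = xd[2], B = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], m = rmean[c], bb = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xs = x.begin() + ((size_t)c + (size_t)C * b) * plane;
      double* ys = y.begin() + ((size_t)c + (size_t)C * b) * plane;
      for (size_t i = 0; i < plane; ++i) ys[i] = g * (xs[i] - m) * inv + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector leaky_fwd(NumericVector x, double slope) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector leaky_bwd(NumericVector x, double slope, NumericVector gy) {
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) gx[i] = x[i] > 0 ? gy[i] : slope * gy[i];
  return gx;
}

// Softmax over the channel dimension of (H, W, C, B).
// [[Rcpp::export]]
NumericVector channel_softmax(NumericVector x) {
  arma::uvec xd = get_dims(x);
  const int C = xd[2], B = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  std::vector<double> buf(C);
  for (int b = 0; b < B; ++b) {
    const double* xs = x.begin() + (size_t)b * plane * C;
    double* ys = y.begin() + (size_t)b * plane * C;
    for (size_t i = 0; i < plane; ++i) {
      double mx = -INFINITY;
      for (int c = 0; c < C; ++c) {
        buf[c] = xs[i + plane * c];
        if (buf[c] > mx) mx = buf[c];
      }
      double s = 0;
      for (int c = 0; c < C; ++c) { buf[c] = std::exp(buf[c] - mx); s += buf[c]; }
      for (int c = 0; c < C; ++c) ys[i + plane * c] = buf[c] / s;
    }
  }
  return y;
}

// Jacobian-vector product of channel softmax: given probabilities p and the
// gradient gp w.r.t. p, return the gradient w.r.t. the logits.
// [[Rcpp::export]]
NumericVector channel_softmax_bwd(NumericVector p, NumericVector gp) {
  arma::uvec xd = get_dims(p);
  const int C = xd[2], B = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  NumericVector gz(p.size()); gz.attr("dim") = p.attr("dim");
  for (int b = 0; b < B; ++b) {
    const double* ps = p.begin() + (size_t)b * plane * C;
    const double* gs = gp.begin() + (size_t)b * plane * C;
    double* os = gz.begin() + (size_t)b * plane * C;
    for (size_t i = 0; i < plane; ++i) {
      double dot = 0;
      for (int c = 0; c < C; ++c) dot += ps[i + plane * c] * gs[i + plane * c];
      for (int c = 0; c < C; ++c)
        os[i + plane * c] = ps[i + plane * c] * (gs[i + plane * c] - dot);
    }
  }
  return gz;
}

// Symmetric Hausdorff distance between two point sets (rows = points).
// [[Rcpp::export]]
double hausdorff_points(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  double hmax = 0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix& P = pass == 0 ? A : B;
    const NumericMatrix& Q = pass == 0 ? B : A;
    const int np = P.nrow(), nq = Q.nrow();
    for (int i = 0; i < np; ++i) {
      double dmin = INFINITY;
      const double px = P(i, 0), py = P(i, 1);
      for (int j = 0; j < nq; ++j) {
        const double dx = px - Q(j, 0), dy = py - Q(j, 1);
        const double d2 = dx * dx + dy * dy;
        if (d2 < dmin) dmin = d2;
        if (dmin == 0) break;
      }
      if (dmin > hmax) hmax = dmin;
    }
  }
  (void)n; (void)m;
  return std::sqrt(hmax);
}

// Concatenate (H, W, C_i, B) arrays along the channel dimension.
// [[Rcpp::export]]
NumericVector concat_channels_cpp(List xs) {
  const int n = xs.size();
  std::vector<NumericVector> vs;
  std::vector<int> cs;
  int H = 0, W = 0, B = 0, Ctot = 0;
  for (int i = 0; i < n; ++i) {
    NumericVector v = xs[i];
    arma::uvec d = get_dims(v);
    if (i == 0) { H = d[0]; W = d[1]; B = d[3]; }
    cs.push_back(d[2]);
    Ctot += d[2];
    vs.push_back(v);
  }
  NumericVector y((size_t)H * W * Ctot * B);
  y.attr("dim") = IntegerVector::create(H, W, Ctot, B);
  const size_t plane = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    size_t at = 0;
    for (int i = 0; i < n; ++i) {
      const size_t len = plane * cs[i];
      std::memcpy(y.begin() + plane * ((size_t)Ctot * b) + plane * at,
                  vs[i].begin() + len * b, sizeof(double) * len);
      at += cs[i];
    }
  }
  return y;
}

// Split a (H, W, C, B) array into per-source channel slabs (adjoint of
// concat for gradients).
// [[Rcpp::export]]
List split_channels_cpp(NumericVector g, IntegerVector sizes) {
  arma::uvec d = get_dims(g);
  const int H = d[0], W = d[1], Ctot = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  List out(sizes.size());
  size_t at = 0;
  for (int i = 0; i < sizes.size(); ++i) {
    const int ci = sizes[i];
    NumericVector p((size_t)H * W * ci * B);
    p.attr("dim") = IntegerVector::create(H, W, ci, B);
    for (int b = 0; b < B; ++b) {
      std::memcpy(p.begin() + plane * (size_t)ci * b,
                  g.begin() + plane * ((size_t)Ctot * b + at),
                  sizeof(double) * plane * ci);
    }
    out[i] = p;
    at += ci;
  }
  return out;
}

// 4-class confusion counts between two integer label maps.
// [[Rcpp::export]]
IntegerMatrix confusion_counts(IntegerVector truth, IntegerVector pred, int C) {
  IntegerMatrix P(C, C);
  for (R_xlen_t i = 0; i < truth.size(); ++i) {
    const int t = truth[i], p = pred[i];
    if (t < 0 || t >= C) stop("confusion_counts: true label %d outside [0, %d)", t, C);
    if (p < 0 || p >= C) stop("confusion_counts: predicted label %d outside [0, %d)", p, C);
    P(t, p) += 1;
  }
  return P;
}
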