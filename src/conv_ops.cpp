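// Low-level tensor kernels for the segmentation network.
//
// Tensor layout (R column-major arrays):
//   feature maps  : dim c(H, W, C, N)   -- height, width, channels, batch
//   conv weights  : dim c(k, k, Cin, Cout)
//   conv bias     : length Cout
// All convolutions have stride 1; spatial size changes only through the
// explicit pooling / upsampling ops. Dilated convolution is realised by
// im2col with a row spacing of `dilation`, so its parameter count is
// independent of the dilation rate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector tensor_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (H, W, C, N)");
  return d;
}

// Fill the transposed im2col matrix, rows = output pixels of the whole
// batch (p = oh + Ho*(ow + Wo*n)), cols = kernel taps r = (c*k + kh)*k + kw.
// Row-contiguous writes and column reads keep this memory-bound step cheap;
// the whole batch then feeds a single gemm.
static void im2col_t(const double* x, int H, int W, int Cin, int N,
                     int k, int dil, int pad, int Ho, int Wo, arma::mat& colt) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < Cin; ++c)
    for (int kh = 0; kh < k; ++kh)
      for (int kw = 0; kw < k; ++kw) {
        const int r = (c * k + kh) * k + kw;
        double* dst0 = colt.colptr(r);
        const int dh = kh * dil - pad;   // ih = oh + dh
        const int dw = kw * dil - pad;   // iw = ow + dw
        const int oh_lo = std::min(std::max(0, -dh), Ho);
        const int oh_hi = std::max(std::min(Ho, H - dh), oh_lo);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + n * HW * Cin + c * HW;
          double* dstn = dst0 + n * HoWo;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow + dw;
            double* dst = dstn + (R_xlen_t)Ho * ow;
            if (iw < 0 || iw >= W) {
              std::fill(dst, dst + Ho, 0.0);
              continue;
            }
            const double* src = xs + (R_xlen_t)H * iw + dh;
            if (oh_lo > 0) std::fill(dst, dst + oh_lo, 0.0);
            if (oh_hi > oh_lo)
              std::copy(src + oh_lo, src + oh_hi, dst + oh_lo);
            if (oh_hi < Ho) std::fill(dst + oh_hi, dst + Ho, 0.0);
          }
        }
      }
}

// Scatter-add the transposed gradient columns back onto the input batch.
static void col2im_t_acc(const arma::mat& dcolt, int H, int W, int Cin, int N,
                         int k, int dil, int pad, int Ho, int Wo, double* dx) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < Cin; ++c)
    for (int kh = 0; kh < k; ++kh)
      for (int kw = 0; kw < k; ++kw) {
        const int r = (c * k + kh) * k + kw;
        const double* src0 = dcolt.colptr(r);
        const int dh = kh * dil - pad;
        const int dw = kw * dil - pad;
        const int oh_lo = std::min(std::max(0, -dh), Ho);
        const int oh_hi = std::max(std::min(Ho, H - dh), oh_lo);
        for (int n = 0; n < N; ++n) {
          double* xs = dx + n * HW * Cin + c * HW;
          const double* srcn = src0 + n * HoWo;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow + dw;
            if (iw < 0 || iw >= W) continue;
            double* dst = xs + (R_xlen_t)H * iw + dh;
            const double* src = srcn + (R_xlen_t)Ho * ow;
            for (int oh = oh_lo; oh < oh_hi; ++oh) dst[oh] += src[oh];
          }
        }
      }
}

// Reshape the (k,k,Cin,Cout) weight array to (Cin*k*k x Cout) gemm form.
static arma::mat weight_matrix_t(const NumericVector& w, int k, int Cin,
                                 int Cout) {
  arma::mat W2t(Cin * k * k, Cout);
  const double* wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          W2t((c * k + kh) * k + kw, co) =
            wp[kh + k * (kw + k * (c + Cin * co))];
  return W2t;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int dilation, int pad) {
  IntegerVector xd = tensor_dim(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1]) stop("weights must have dim (k, k, Cin, Cout)");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch: input has %d channels, kernel expects %d",
                         Cin, (int)wd[2]);
  const int Ho = H + 2 * pad - dilation * (k - 1);
  const int Wo = W + 2 * pad - dilation * (k - 1);
  if (Ho <= 0 || Wo <= 0) stop("kernel footprint exceeds padded input");
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;

  arma::mat W2t = weight_matrix_t(w, k, Cin, Cout);
  arma::mat colt(HoWo * N, (R_xlen_t)Cin * k * k);
  im2col_t(x.begin(), H, W, Cin, N, k, dilation, pad, Ho, Wo, colt);
  arma::mat om = colt * W2t;  // (N*Ho*Wo) x Cout

  NumericVector out(HoWo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* src = om.colptr(co);
    const double bias = b[co];
    for (int n = 0; n < N; ++n) {
      double* dst = op + HoWo * (co + (R_xlen_t)Cout * n);
      const double* s = src + HoWo * n;
      for (R_xlen_t p = 0; p < HoWo; ++p) dst[p] = s[p] + bias;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector dout, NumericVector x, NumericVector w,
                   int dilation, int pad) {
  IntegerVector xd = tensor_dim(x), od = tensor_dim(dout);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = od[0], Wo = od[1];
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;

  arma::mat W2t = weight_matrix_t(w, k, Cin, Cout);

  // gradient w.r.t. output, rows aligned with the im2col row order
  arma::mat dmt(HoWo * N, Cout);
  const double* dp = dout.begin();
  for (int co = 0; co < Cout; ++co) {
    double* dst = dmt.colptr(co);
    for (int n = 0; n < N; ++n)
      std::copy(dp + HoWo * (co + (R_xlen_t)Cout * n),
                dp + HoWo * (co + (R_xlen_t)Cout * n) + HoWo,
                dst + HoWo * n);
  }

  arma::mat colt(HoWo * N, (R_xlen_t)Cin * k * k);
  im2col_t(x.begin(), H, W, Cin, N, k, dilation, pad, Ho, Wo, colt);
  arma::mat dW2t = colt.t() * dmt;            // (Cin*k*k) x Cout
  arma::rowvec db = arma::sum(dmt, 0);
  arma::mat dcolt = dmt * W2t.t();            // rows x (Cin*k*k)

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  col2im_t_acc(dcolt, H, W, Cin, N, k, dilation, pad, Ho, Wo, dx.begin());

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  double* dwp = dw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          dwp[kh + k * (kw + k * (c + Cin * co))] =
            dW2t((c * k + kh) * k + kw, co);

  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = db(co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("max-pool input dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;

  NumericVector out(Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(out.size());  // 0-based linear index into x

  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          R_xlen_t i00 = base + 2 * oh + H * (2 * ow);
          R_xlen_t best = i00;
          double v = xp[i00];
          const R_xlen_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > v) { v = xp[cand[t]]; best = cand[t]; }
          op[o] = v;
          ip[o] = (int)best;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dout, IntegerVector idx,
                              IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dp = dx.begin();
  const double* gp = dout.begin();
  const int* ip = idx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) dp[ip[i]] += gp[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("average-pool input dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          R_xlen_t i00 = base + 2 * oh + H * (2 * ow);
          op[o] = 0.25 * (xp[i00] + xp[i00 + 1] + xp[i00 + H] + xp[i00 + H + 1]);
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector dout, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double* dp = dx.begin();
  const double* gp = dout.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          R_xlen_t i00 = base + 2 * oh + H * (2 * ow);
          const double g = 0.25 * gp[o];
          dp[i00] += g; dp[i00 + 1] += g; dp[i00 + H] += g; dp[i00 + H + 1] += g;
        }
    }
  return dx;
}

// Bilinear x2 upsampling, half-pixel centres (align_corners = false).
static void bilinear2_weights(int H, std::vector<int>& i0, std::vector<int>& i1,
                              std::vector<double>& w0, std::vector<double>& w1) {
  const int Ho = 2 * H;
  i0.resize(Ho); i1.resize(Ho); w0.resize(Ho); w1.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    int a = (int)std::floor(src);
    int b = std::min(a + 1, H - 1);
    double f = src - a;
    i0[i] = a; i1[i] = b; w1[i] = f; w0[i] = 1.0 - f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw0, rw1, cw0, cw1;
  bilinear2_weights(H, r0, r1, rw0, rw1);
  bilinear2_weights(W, c0, c1, cw0, cw1);

  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double* xs = xp + s * H * W;
    double* os = op + s * (R_xlen_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* colA = xs + c0[j] * H;
      const double* colB = xs + c1[j] * H;
      for (int i = 0; i < Ho; ++i)
        os[i + (R_xlen_t)Ho * j] =
          cw0[j] * (rw0[i] * colA[r0[i]] + rw1[i] * colA[r1[i]]) +
          cw1[j] * (rw0[i] * colB[r0[i]] + rw1[i] * colB[r1[i]]);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dout, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw0, rw1, cw0, cw1;
  bilinear2_weights(H, r0, r1, rw0, rw1);
  bilinear2_weights(W, c0, c1, cw0, cw1);

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* gp = dout.begin();
  double* dp = dx.begin();
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    double* ds = dp + s * (R_xlen_t)H * W;
    const double* gs = gp + s * (R_xlen_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gs[i + (R_xlen_t)Ho * j];
        ds[r0[i] + H * c0[j]] += cw0[j] * rw0[i] * g;
        ds[r1[i] + H * c0[j]] += cw0[j] * rw1[i] * g;
        ds[r0[i] + H * c1[j]] += cw1[j] * rw0[i] * g;
        ds[r1[i] + H * c1[j]] += cw1[j] * rw1[i] * g;
      }
  }
  return dx;
}

// Per-channel sum over (H, W, N) — batch-norm reductions.
// [[Rcpp::export]]
NumericVector cpp_ch_sum(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* s = xp + HW * (c + (R_xlen_t)C * n);
      double acc = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) acc += s[i];
      out[c] += acc;
    }
  return out;
}

// Broadcast a one-channel gate over all channels: out = x * gate.
// [[Rcpp::export]]
NumericVector cpp_gate_mul_fw(NumericVector gate, NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  const double* gp = gate.begin();
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* g = gp + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* s = xp + HW * (c + (R_xlen_t)C * n);
      double* d = op + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) d[i] = s[i] * g[i];
    }
  }
  return out;
}

// Gradients of the gate product: dx = dout * gate; dgate = sum_c dout * x.
// [[Rcpp::export]]
List cpp_gate_mul_bw(NumericVector dout, NumericVector gate, NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgate(gate.size());
  dgate.attr("dim") = gate.attr("dim");
  const double* gp = gate.begin();
  const double* xp = x.begin();
  const double* op = dout.begin();
  double* dxp = dx.begin();
  double* dgp = dgate.begin();
  for (int n = 0; n < N; ++n) {
    const double* g = gp + HW * n;
    double* dg = dgp + HW * n;
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* s = xp + off;
      const double* o = op + off;
      double* d = dxp + off;
      for (R_xlen_t i = 0; i < HW; ++i) {
        d[i] = o[i] * g[i];
        dg[i] += o[i] * s[i];
      }
    }
  }
  return List::create(_["dgate"] = dgate, _["dx"] = dx);
}
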