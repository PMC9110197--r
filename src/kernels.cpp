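// Compiled tensor kernels for the CNN engine.
//
// Array layout convention (matches R's column-major arrays):
//   activations  x : dim (H, W, C, N)
//   conv weights W : dim (K, K, C_in, C_out)
// Stride-1 convolutions use "same" zero padding of (K-1)/2; the transpose
// convolution is the 2x2 stride-2 upsampler used by the decoders, with an
// explicit output size so odd target sizes (12 -> 25) are representable.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// colsT: (H*W*N) x (K*K*C); row j enumerates (h fastest, then w, then n),
// column r = kh + K*kw + K*K*c. Transposed layout keeps every write a
// contiguous run down the image columns (memcpy-able).
static void im2colT(const double* x, int H, int W, int C, int N, int K,
                    int pad, arma::mat& colsT) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const size_t r = (size_t)kh + K * kw + (size_t)K * K * c;
        double* dst = colsT.colptr(r);
        const int h0 = std::max(0, pad - kh);
        const int h1 = std::min(H, H + pad - kh);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + HW * (c + (size_t)C * n);
          for (int w = 0; w < W; ++w) {
            const int ww = w + kw - pad;
            double* d2 = dst + ((size_t)n * W + w) * H;
            if (ww < 0 || ww >= W) {
              std::memset(d2, 0, sizeof(double) * H);
              continue;
            }
            const double* src = xc + (size_t)ww * H + (kh - pad);
            if (h0 > 0) std::memset(d2, 0, sizeof(double) * h0);
            if (h1 > h0)
              std::memcpy(d2 + h0, src + h0, sizeof(double) * (h1 - h0));
            if (h1 < H) std::memset(d2 + h1, 0, sizeof(double) * (H - h1));
          }
        }
      }
}

// Scatter-add of the transposed column buffer back into image layout.
static void col2imT(const arma::mat& colsT, int H, int W, int C, int N, int K,
                    int pad, double* dx) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const size_t r = (size_t)kh + K * kw + (size_t)K * K * c;
        const double* src = colsT.colptr(r);
        const int h0 = std::max(0, pad - kh);
        const int h1 = std::min(H, H + pad - kh);
        for (int n = 0; n < N; ++n) {
          double* xc = dx + HW * (c + (size_t)C * n);
          for (int w = 0; w < W; ++w) {
            const int ww = w + kw - pad;
            if (ww < 0 || ww >= W) continue;
            const double* s2 = src + ((size_t)n * W + w) * H;
            double* d2 = xc + (size_t)ww * H + (kh - pad);
            for (int h = h0; h < h1; ++h) d2[h] += s2[h];
          }
        }
      }
}

// Gather gy (H, W, Cout, N) into (H*W*N) x Cout.
static void gather_gT(const double* gp, int H, int W, int Cout, int N,
                      arma::mat& G) {
  const size_t HW = (size_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    double* dst = G.colptr(co);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst + n * HW, gp + HW * (co + (size_t)Cout * n),
                  sizeof(double) * HW);
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != K || Cin != C) stop("weight dims do not match input");
  const int pad = (K - 1) / 2;
  const size_t P = (size_t)H * W * N, HW = (size_t)H * W;

  arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Cout, false, true);
  arma::mat out;  // P x Cout
  if (K == 1) {
    arma::mat Xt(P, C);
    gather_gT(x.begin(), H, W, C, N, Xt);
    out = Xt * Wm;
  } else {
    arma::mat colsT(P, (size_t)K * K * C);
    im2colT(x.begin(), H, W, C, N, K, pad, colsT);
    out = colsT * Wm;
  }

  NumericVector y(Cout * P);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* src = out.colptr(co);
    const double bc = b[co];
    for (int n = 0; n < N; ++n) {
      double* dst = yp + HW * (co + (size_t)Cout * n);
      const double* s2 = src + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) dst[i] = s2[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int K = wd[0], Cout = wd[3];
  const int pad = (K - 1) / 2;
  const size_t P = (size_t)H * W * N;

  arma::mat G(P, Cout);
  gather_gT(gy.begin(), H, W, Cout, N, G);
  arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Cout, false, true);
  arma::rowvec db = arma::sum(G, 0);

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  arma::mat dW;
  if (K == 1) {
    arma::mat Xt(P, C);
    gather_gT(x.begin(), H, W, C, N, Xt);
    dW = Xt.t() * G;                      // C x Cout
    arma::mat dXt = G * Wm.t();           // P x C
    double* dxp = dx.begin();
    const size_t HW = (size_t)H * W;
    for (int c = 0; c < C; ++c) {
      const double* src = dXt.colptr(c);
      for (int n = 0; n < N; ++n)
        std::memcpy(dxp + HW * (c + (size_t)C * n), src + (size_t)n * HW,
                    sizeof(double) * HW);
    }
  } else {
    arma::mat colsT(P, (size_t)K * K * C);
    im2colT(x.begin(), H, W, C, N, K, pad, colsT);
    dW = colsT.t() * G;                   // (K*K*C) x Cout
    arma::mat dcolsT = G * Wm.t();        // P x (K*K*C)
    col2imT(dcolsT, H, W, C, N, K, pad, dx.begin());
  }

  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = w.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 stride-2 transpose convolution; w dim (2, 2, C_in, C_out).
// Output (oh, ow) with oh in {2H, 2H+1}: the extra row/column receives only
// the bias (the same convention as output_padding in mainstream frameworks).
// [[Rcpp::export]]
NumericVector cpp_convt2x2_forward(NumericVector x, NumericVector w,
                                   NumericVector b, int oh, int ow) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != C) stop("bad transpose-conv weight");
  if (oh < 2 * H || oh > 2 * H + 1 || ow < 2 * W || ow > 2 * W + 1)
    stop("output size must be 2*in or 2*in+1");

  const size_t P = (size_t)H * W * N, HW = (size_t)H * W,
               OHW = (size_t)oh * ow;
  // Gather input as (C x P)
  arma::mat X(C, P);
  const double* xp = x.begin();
  for (size_t j = 0; j < P; ++j) {
    const size_t n = j / HW, hw = j % HW;
    for (int c = 0; c < C; ++c) X(c, j) = xp[hw + HW * (c + (size_t)C * n)];
  }
  arma::mat Wm(const_cast<double*>(w.begin()), 4, (size_t)C * Cout, false, true);

  NumericVector y(OHW * Cout * N);
  y.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* ys = yp + OHW * (co + (size_t)Cout * n);
      for (size_t i = 0; i < OHW; ++i) ys[i] = b[co];
    }

  for (int kw = 0; kw < 2; ++kw)
    for (int kh = 0; kh < 2; ++kh) {
      const int kidx = kh + 2 * kw;
      // Wk: C x Cout slice for this kernel position
      arma::mat Wk(C, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c) Wk(c, co) = Wm(kidx, c + (size_t)C * co);
      arma::mat Yk = Wk.t() * X;  // Cout x P
      for (size_t j = 0; j < P; ++j) {
        const size_t n = j / HW, hw = j % HW;
        const int h = (int)(hw % H), ww = (int)(hw / H);
        const size_t oi = (size_t)(2 * h + kh) + (size_t)oh * (2 * ww + kw);
        for (int co = 0; co < Cout; ++co)
          yp[oi + OHW * (co + (size_t)Cout * n)] += Yk(co, j);
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2x2_backward(NumericVector x, NumericVector w, NumericVector gy,
                           int oh, int ow) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const size_t P = (size_t)H * W * N, HW = (size_t)H * W,
               OHW = (size_t)oh * ow;

  arma::mat X(C, P);
  const double* xp = x.begin();
  for (size_t j = 0; j < P; ++j) {
    const size_t n = j / HW, hw = j % HW;
    for (int c = 0; c < C; ++c) X(c, j) = xp[hw + HW * (c + (size_t)C * n)];
  }
  arma::mat Wm(const_cast<double*>(w.begin()), 4, (size_t)C * Cout, false, true);

  arma::mat dX(C, P, arma::fill::zeros);
  NumericVector dW(w.size());
  dW.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  const double* gp = gy.begin();

  // db: total gradient per output channel (includes padded row/col).
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* gs = gp + OHW * (co + (size_t)Cout * n);
      double s = 0.0;
      for (size_t i = 0; i < OHW; ++i) s += gs[i];
      db[co] += s;
    }

  double* dWp = dW.begin();
  for (int kw = 0; kw < 2; ++kw)
    for (int kh = 0; kh < 2; ++kh) {
      const int kidx = kh + 2 * kw;
      arma::mat Gk(Cout, P);
      for (size_t j = 0; j < P; ++j) {
        const size_t n = j / HW, hw = j % HW;
        const int h = (int)(hw % H), ww = (int)(hw / H);
        const size_t oi = (size_t)(2 * h + kh) + (size_t)oh * (2 * ww + kw);
        for (int co = 0; co < Cout; ++co)
          Gk(co, j) = gp[oi + OHW * (co + (size_t)Cout * n)];
      }
      arma::mat Wk(C, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c) Wk(c, co) = Wm(kidx, c + (size_t)C * co);
      dX += Wk * Gk;
      arma::mat dWk = X * Gk.t();  // C x Cout
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c)
          dWp[kidx + 4 * (c + (size_t)C * co)] += dWk(c, co);
    }

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  double* dxp = dx.begin();
  for (size_t j = 0; j < P; ++j) {
    const size_t n = j / HW, hw = j % HW;
    for (int c = 0; c < C; ++c) dxp[hw + HW * (c + (size_t)C * n)] = dX(c, j);
  }
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// 2x2 stride-2 max pooling with floor division (25 -> 12 drops the last
// row/column, matching the reference encoder size schedule).
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W, OHW = (size_t)H2 * W2;
  NumericVector y(OHW * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = HW * (c + (size_t)C * n);
      const size_t yoff = OHW * (c + (size_t)C * n);
      for (int w2 = 0; w2 < W2; ++w2)
        for (int h2 = 0; h2 < H2; ++h2) {
          double best = -INFINITY;
          size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t li = xoff + (size_t)(2 * h2 + dh) +
                                (size_t)H * (2 * w2 + dw);
              if (xp[li] > best) { best = xp[li]; bi = li; }
            }
          yp[yoff + h2 + (size_t)H2 * w2] = best;
          ip[yoff + h2 + (size_t)H2 * w2] = (int)bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector xdim) {
  size_t total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= (size_t)xdim[i];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* gp = gy.begin();
  const int* ip = INTEGER(idx);
  const R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ip[i]] += gp[i];
  return dx;
}
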