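// Low-level numerical kernels for the segmentation network and region labeling.
// Tensor layout everywhere: column-major R arrays dim (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col: rows = output positions m = ho + Ho*(wo + Wo*n), cols = kernel taps
// kr + kh*(kc + kw*ci). Out-of-bounds taps (zero padding) stay 0.
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad) {
  const int Ho = out_dim(H, kh, stride, pad);
  const int Wo = out_dim(W, kw, stride, pad);
  const arma::uword M = (arma::uword)Ho * Wo * N;
  arma::mat cols(M, (arma::uword)kh * kw * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const arma::uword col = kr + (arma::uword)kh * (kc + (arma::uword)kw * ci);
        double* dst = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* xn = x + (arma::uword)H * W * ((arma::uword)C * n + ci);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kc;
            if (wi < 0 || wi >= W) continue;
            const double* xc = xn + (arma::uword)H * wi;
            double* d = dst + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + kr;
              if (hi >= 0 && hi < H) d[ho] = xc[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of column matrix back to image gradient (transpose of im2col)
static void col2im(const arma::mat& cols, double* dx, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad) {
  const int Ho = out_dim(H, kh, stride, pad);
  const int Wo = out_dim(W, kw, stride, pad);
  for (int ci = 0; ci < C; ++ci) {
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const arma::uword col = kr + (arma::uword)kh * (kc + (arma::uword)kw * ci);
        const double* src = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* xn = dx + (arma::uword)H * W * ((arma::uword)C * n + ci);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kc;
            if (wi < 0 || wi >= W) continue;
            double* xc = xn + (arma::uword)H * wi;
            const double* s = src + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + kr;
              if (hi >= 0 && hi < H) xc[hi] += s[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Co = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  arma::mat cols = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * Cin, Co, false, true);
  arma::mat out = cols * Wm;                       // (M, Co)
  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* src = out.colptr(co) + (arma::uword)Ho * Wo * n;
      double* dst = yp + (arma::uword)Ho * Wo * (co + (arma::uword)Co * n);
      const double b = bias[co];
      for (arma::uword i = 0; i < (arma::uword)Ho * Wo; ++i) dst[i] = src[i] + b;
    }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const arma::uword M = (arma::uword)Ho * Wo * N;
  // permute dy (Ho,Wo,Co,N) -> (M, Co)
  arma::mat dyM(M, Co);
  const double* dp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* src = dp + (arma::uword)Ho * Wo * (co + (arma::uword)Co * n);
      double* dst = dyM.colptr(co) + (arma::uword)Ho * Wo * n;
      std::copy(src, src + (arma::uword)Ho * Wo, dst);
    }
  arma::mat cols = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * C, Co, false, true);
  arma::mat dW = cols.t() * dyM;                   // (K, Co)
  arma::rowvec db = arma::sum(dyM, 0);
  arma::mat dcols = dyM * Wm.t();                  // (M, K)
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  col2im(dcols, dx.begin(), H, W, C, N, kh, kw, stride, pad);
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  arma::uword o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const arma::uword base = (arma::uword)H * W * (c + (arma::uword)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bi = 0;
          for (int kc = 0; kc < k; ++kc) {
            const int wi = wo * stride - pad + kc;
            if (wi < 0 || wi >= W) continue;
            for (int kr = 0; kr < k; ++kr) {
              const int hi = ho * stride - pad + kr;
              if (hi < 0 || hi >= H) continue;
              const arma::uword idx = base + hi + (arma::uword)H * wi;
              if (xp[idx] > best) { best = xp[idx]; bi = idx; }
            }
          }
          // column-major output order is (ho fastest) but we iterate wo outer;
          // compute target index explicitly
          const arma::uword yi = ho + (arma::uword)Ho * (wo + (arma::uword)Wo * (c + (arma::uword)C * n));
          yp[yi] = best;
          ap[yi] = (int)bi;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector argmax, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const double* dp = dy.begin();
  const int* ap = argmax.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ap[i]] += dp[i];
  return dx;
}

// 8-connected component labeling of a logical/integer matrix (foreground != 0).
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int d = 0; d < 8; ++d) {
          const int qi = pi + dr[d], qj = pj + dc[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (m(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  return lab;
}
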