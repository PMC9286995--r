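#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gather the nine 3x3-neighbourhood shifts of a channel-last feature tensor
// x (H, W, N, C) into the (H*W*N) x (9*C) im2col matrix used by the
// shifted-GEMM convolutions. Offset order matches the R side: di (row
// offset) outer, dj inner, each over -1..1; zero padding at the frame
// border. Columns are blocked per offset, channels contiguous inside a
// block.

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int N, int C) {
  const R_xlen_t n = (R_xlen_t)H * W * N;
  NumericMatrix out(n, 9 * C);
  const double* px = x.begin();
  double* po = out.begin();
  int k = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj, ++k) {
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      for (int c = 0; c < C; ++c) {
        double* col = po + (R_xlen_t)(k * C + c) * n;
        const double* xc = px + (R_xlen_t)c * n;
        for (int nn = 0; nn < N; ++nn) {
          const double* xn = xc + (R_xlen_t)nn * H * W;
          double* coln = col + (R_xlen_t)nn * H * W;
          for (int j = 0; j < W; ++j) {
            double* dst = coln + (R_xlen_t)j * H;
            const int sj = j + dj;
            if (sj < 0 || sj >= W) {
              std::fill(dst, dst + H, 0.0);
              continue;
            }
            const double* src = xn + (R_xlen_t)sj * H;
            if (i0 > 0) std::fill(dst, dst + i0, 0.0);
            if (i1 < H) std::fill(dst + i1, dst + H, 0.0);
            if (i1 > i0) std::copy(src + i0 + di, src + i1 + di, dst + i0);
          }
        }
      }
    }
  }
  return out;
}

// In-place per-column bias add on a freshly allocated GEMM result.

// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix y, NumericVector b) {
  const R_xlen_t n = y.nrow();
  const int C = y.ncol();
  double* p = y.begin();
  for (int c = 0; c < C; ++c) {
    const double bv = b[c];
    double* col = p + (R_xlen_t)c * n;
    for (R_xlen_t r = 0; r < n; ++r) col[r] += bv;
  }
}

// Per-column mean and (population) variance in one pass.

// [[Rcpp::export]]
List col_mean_var_cpp(NumericMatrix m) {
  const R_xlen_t n = m.nrow();
  const int C = m.ncol();
  NumericVector mu(C), v(C);
  const double* p = m.begin();
  for (int c = 0; c < C; ++c) {
    const double* col = p + (R_xlen_t)c * n;
    double s = 0.0;
    for (R_xlen_t r = 0; r < n; ++r) s += col[r];
    const double mc = s / n;
    double ss = 0.0;
    for (R_xlen_t r = 0; r < n; ++r) { const double d = col[r] - mc; ss += d * d; }
    mu[c] = mc; v[c] = ss / n;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// Batch-norm forward core: xhat = (m - mu) * invstd, y = xhat*gamma + beta.

// [[Rcpp::export]]
List bn_core_cpp(NumericMatrix m, NumericVector mu, NumericVector invstd,
                 NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = m.nrow();
  const int C = m.ncol();
  NumericMatrix xhat(n, C), y(n, C);
  const double* pm = m.begin();
  double* px = xhat.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double mc = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
    const double* col = pm + (R_xlen_t)c * n;
    double* xc = px + (R_xlen_t)c * n;
    double* yc = py + (R_xlen_t)c * n;
    for (R_xlen_t r = 0; r < n; ++r) {
      const double xh = (col[r] - mc) * is;
      xc[r] = xh;
      yc[r] = xh * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Batch-norm backward core. Returns dx plus the parameter gradients.

// [[Rcpp::export]]
List bn_bwd_cpp(NumericMatrix dm, NumericMatrix xhat, NumericVector gamma,
                NumericVector invstd, bool training) {
  const R_xlen_t n = dm.nrow();
  const int C = dm.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  const double* pd = dm.begin();
  const double* px = xhat.begin();
  double* po = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], is = invstd[c];
    const double* dc = pd + (R_xlen_t)c * n;
    const double* xc = px + (R_xlen_t)c * n;
    double* oc = po + (R_xlen_t)c * n;
    double sd = 0.0, sdx = 0.0;
    for (R_xlen_t r = 0; r < n; ++r) {
      sd += dc[r];
      sdx += dc[r] * xc[r];
    }
    dbeta[c] = sd; dgamma[c] = sdx;
    if (training) {
      const double t1 = g * sd / n, t2 = g * sdx / n;
      for (R_xlen_t r = 0; r < n; ++r)
        oc[r] = (g * dc[r] - t1 - xc[r] * t2) * is;
    } else {
      for (R_xlen_t r = 0; r < n; ++r) oc[r] = g * dc[r] * is;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Direct depthwise 3x3 convolution on a channel-last (H, W, N, C) tensor:
// out[i,j,n,c] = sum_k x[i+di_k, j+dj_k, n, c] * w[k, c], zero-padded.
// With flip the adjoint kernel (reversed offsets) is applied.

// [[Rcpp::export]]
NumericVector dwconv3_direct_cpp(NumericVector x, int H, int W, int N, int C,
                                 NumericMatrix w, bool flip) {
  NumericVector out((R_xlen_t)H * W * N * C);
  const double* px = x.begin();
  double* po = out.begin();
  int k = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj, ++k) {
      const int kw = flip ? 8 - k : k;
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      if (i1 <= i0) continue;
      for (int c = 0; c < C; ++c) {
        const double wv = w(kw, c);
        if (wv == 0.0) continue;
        const R_xlen_t cbase = (R_xlen_t)c * H * W * N;
        for (int nn = 0; nn < N; ++nn) {
          const R_xlen_t nbase = cbase + (R_xlen_t)nn * H * W;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj;
            if (sj < 0 || sj >= W) continue;
            const double* src = px + nbase + (R_xlen_t)sj * H + di;
            double* dst = po + nbase + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) dst[i] += wv * src[i];
          }
        }
      }
    }
  }
  return out;
}

// Depthwise weight gradient computed directly from the input tensor and the
// output gradient (both (H, W, N, C)).

// [[Rcpp::export]]
NumericMatrix dwgrad3_direct_cpp(NumericVector x, int H, int W, int N, int C,
                                 NumericVector dy) {
  NumericMatrix dw(9, C);
  const double* px = x.begin();
  const double* pd = dy.begin();
  int k = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj, ++k) {
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      if (i1 <= i0) continue;
      for (int c = 0; c < C; ++c) {
        const R_xlen_t cbase = (R_xlen_t)c * H * W * N;
        double acc = 0.0;
        for (int nn = 0; nn < N; ++nn) {
          const R_xlen_t nbase = cbase + (R_xlen_t)nn * H * W;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj;
            if (sj < 0 || sj >= W) continue;
            const double* src = px + nbase + (R_xlen_t)sj * H + di;
            const double* dc = pd + nbase + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) acc += src[i] * dc[i];
          }
        }
        dw(k, c) += acc;
      }
    }
  }
  return dw;
}
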