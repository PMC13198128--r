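// Hot-path kernels for the autodiff engine: row-wise layer normalization,
// fused multi-head self-attention over a packed QKV block, and the
// sigmoid-form GELU. Everything else stays in R; these three dominate the
// per-step cost of CPU pretraining.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List layernorm_fwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
                   double eps) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix y(n, d), xhat(n, d);
  NumericVector inv(n);
  std::vector<double> mu(n, 0.0), va(n, 0.0);
  const double* X = x.begin();
  for (int j = 0; j < d; ++j) {
    const double* xc = X + (size_t)j * n;
    for (int i = 0; i < n; ++i) mu[i] += xc[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= d;
  for (int j = 0; j < d; ++j) {
    const double* xc = X + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double c = xc[i] - mu[i];
      va[i] += c * c;
    }
  }
  for (int i = 0; i < n; ++i) inv[i] = 1.0 / std::sqrt(va[i] / d + eps);
  double* Y = y.begin();
  double* XH = xhat.begin();
  for (int j = 0; j < d; ++j) {
    const double* xc = X + (size_t)j * n;
    double* yc = Y + (size_t)j * n;
    double* xhc = XH + (size_t)j * n;
    const double gj = gamma[j], bj = beta[j];
    for (int i = 0; i < n; ++i) {
      const double xh = (xc[i] - mu[i]) * inv[i];
      xhc[i] = xh;
      yc[i] = xh * gj + bj;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List layernorm_bwd(NumericMatrix g, NumericMatrix xhat, NumericVector inv,
                   NumericVector gamma) {
  const int n = g.nrow(), d = g.ncol();
  NumericMatrix dx(n, d);
  NumericVector dgamma(d), dbeta(d);
  std::vector<double> m1(n, 0.0), m2(n, 0.0);
  const double* G = g.begin();
  const double* XH = xhat.begin();
  for (int j = 0; j < d; ++j) {
    const double* gc = G + (size_t)j * n;
    const double* xhc = XH + (size_t)j * n;
    const double gj = gamma[j];
    double dg = 0.0, db = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dxh = gc[i] * gj;
      m1[i] += dxh;
      m2[i] += dxh * xhc[i];
      dg += gc[i] * xhc[i];
      db += gc[i];
    }
    dgamma[j] = dg;
    dbeta[j] = db;
  }
  for (int i = 0; i < n; ++i) { m1[i] /= d; m2[i] /= d; }
  double* DX = dx.begin();
  for (int j = 0; j < d; ++j) {
    const double* gc = G + (size_t)j * n;
    const double* xhc = XH + (size_t)j * n;
    double* dxc = DX + (size_t)j * n;
    const double gj = gamma[j];
    for (int i = 0; i < n; ++i) {
      dxc[i] = (gc[i] * gj - m1[i] - xhc[i] * m2[i]) * inv[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Multi-head attention over a packed (B*L) x 3d QKV matrix, record-major.
// Per-(record, head) blocks are staged into contiguous row-major scratch
// buffers so the O(L^2 dh) inner loops run stride-1 (R matrices are
// column-major; naive indexing thrashes the cache here).
// Returns the (B*L) x d context and the softmax matrices for backward.
// [[Rcpp::export]]
List attn_qkv_fwd(NumericMatrix qkv, int B, int L, int H, LogicalVector valid) {
  const int n = qkv.nrow();
  const int d = qkv.ncol() / 3;
  const int dh = d / H;
  const double scl = 1.0 / std::sqrt((double)dh);
  NumericMatrix out(B * L, d);
  List attn(B * H);
  std::vector<double> q(L * dh), k(L * dh), v(L * dh), S(L * L);
  const double* X = qkv.begin();
  double* O = out.begin();
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh;
      // stage row-major copies of this block's Q, K, V
      for (int c = 0; c < dh; ++c) {
        const double* qc = X + (size_t)(c0 + c) * n + r0;
        const double* kc = X + (size_t)(d + c0 + c) * n + r0;
        const double* vc = X + (size_t)(2 * d + c0 + c) * n + r0;
        for (int i = 0; i < L; ++i) {
          q[i * dh + c] = qc[i];
          k[i * dh + c] = kc[i];
          v[i * dh + c] = vc[i];
        }
      }
      NumericMatrix A(L, L);  // stored transposed: A(j, i) = weight of key j for query i
      for (int i = 0; i < L; ++i) {
        const double* qi = &q[i * dh];
        double mx = -INFINITY;
        for (int j = 0; j < L; ++j) {
          double s;
          if (!valid[r0 + j]) {
            s = -INFINITY;
          } else {
            s = 0.0;
            const double* kj = &k[j * dh];
            for (int c = 0; c < dh; ++c) s += qi[c] * kj[c];
            s *= scl;
          }
          S[j] = s;
          if (s > mx) mx = s;
        }
        double z = 0.0;
        for (int j = 0; j < L; ++j) {
          const double e = std::isfinite(S[j]) ? std::exp(S[j] - mx) : 0.0;
          S[j] = e;
          z += e;
        }
        double* Ai = &A[(size_t)i * L];
        for (int j = 0; j < L; ++j) Ai[j] = S[j] / z;
        // context row i: sum_j a_ij v_j, accumulated per output column
        for (int c = 0; c < dh; ++c) {
          double acc = 0.0;
          for (int j = 0; j < L; ++j) acc += Ai[j] * v[j * dh + c];
          O[(size_t)(c0 + c) * (B * L) + r0 + i] = acc;
        }
      }
      attn[b * H + h] = A;
    }
  }
  return List::create(_["out"] = out, _["attn"] = attn);
}

// [[Rcpp::export]]
NumericMatrix attn_qkv_bwd(NumericMatrix g, NumericMatrix qkv, List attn,
                           int B, int L, int H) {
  const int n = qkv.nrow();
  const int d = qkv.ncol() / 3;
  const int dh = d / H;
  const double scl = 1.0 / std::sqrt((double)dh);
  NumericMatrix dqkv(B * L, 3 * d);
  std::vector<double> q(L * dh), k(L * dh), v(L * dh), gb(L * dh);
  std::vector<double> dq(L * dh), dk(L * dh), dv(L * dh), dA(L), dS(L);
  const double* X = qkv.begin();
  const double* G = g.begin();
  double* D = dqkv.begin();
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh;
      for (int c = 0; c < dh; ++c) {
        const double* qc = X + (size_t)(c0 + c) * n + r0;
        const double* kc = X + (size_t)(d + c0 + c) * n + r0;
        const double* vc = X + (size_t)(2 * d + c0 + c) * n + r0;
        const double* gc = G + (size_t)(c0 + c) * (B * L) + r0;
        for (int i = 0; i < L; ++i) {
          q[i * dh + c] = qc[i];
          k[i * dh + c] = kc[i];
          v[i * dh + c] = vc[i];
          gb[i * dh + c] = gc[i];
        }
      }
      std::fill(dq.begin(), dq.end(), 0.0);
      std::fill(dk.begin(), dk.end(), 0.0);
      std::fill(dv.begin(), dv.end(), 0.0);
      NumericMatrix A = attn[b * H + h];  // A[i * L + j]
      const double* Ap = A.begin();
      for (int i = 0; i < L; ++i) {
        const double* Ai = Ap + (size_t)i * L;
        const double* gi = &gb[i * dh];
        double dot = 0.0;
        for (int j = 0; j < L; ++j) {
          const double* vj = &v[j * dh];
          double da = 0.0;
          for (int c = 0; c < dh; ++c) da += gi[c] * vj[c];
          dA[j] = da;
          dot += da * Ai[j];
        }
        for (int j = 0; j < L; ++j) {
          const double a = Ai[j];
          dS[j] = a * (dA[j] - dot) * scl;
          double* dvj = &dv[j * dh];
          for (int c = 0; c < dh; ++c) dvj[c] += a * gi[c];
        }
        const double* qi = &q[i * dh];
        double* dqi = &dq[i * dh];
        for (int j = 0; j < L; ++j) {
          const double ds = dS[j];
          if (ds == 0.0) continue;
          const double* kj = &k[j * dh];
          double* dkj = &dk[j * dh];
          for (int c = 0; c < dh; ++c) {
            dqi[c] += ds * kj[c];
            dkj[c] += ds * qi[c];
          }
        }
      }
      for (int c = 0; c < dh; ++c) {
        double* dqc = D + (size_t)(c0 + c) * (B * L) + r0;
        double* dkc = D + (size_t)(d + c0 + c) * (B * L) + r0;
        double* dvc = D + (size_t)(2 * d + c0 + c) * (B * L) + r0;
        for (int i = 0; i < L; ++i) {
          dqc[i] = dq[i * dh + c];
          dkc[i] = dk[i * dh + c];
          dvc[i] = dv[i * dh + c];
        }
      }
    }
  }
  return dqkv;
}

// [[Rcpp::export]]
List gelu_fwd(NumericMatrix x) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix y(n, d), dydx(n, d);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) {
      const double v = x(i, j);
      const double s = 1.0 / (1.0 + std::exp(-1.702 * v));
      y(i, j) = v * s;
      dydx(i, j) = s + 1.702 * v * s * (1.0 - s);
    }
  }
  return List::create(_["y"] = y, _["dydx"] = dydx);
}

// y = x + column-broadcast bias
// [[Rcpp::export]]
NumericMatrix bias_add(NumericMatrix x, NumericVector b) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix y(n, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      y(i, j) = x(i, j) + b[j];
  return y;
}
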