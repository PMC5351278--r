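// Compiled kernels: emission log-likelihood matrices, fused posterior-
// weighted column sums (objectives and derivatives for the Newton M-step),
// and the scaled forward-backward recursion over the factorized
// (state x cluster) transition kernel.

#include <Rcpp.h>
using namespace Rcpp;

// negative-binomial log-pmf matrix, one column per joint state:
// size r_j, success probability p_j, evaluated at counts d.
// lgamma(d + r_j) is tabulated over 0..max(d) per column.
// [[Rcpp::export]]
NumericMatrix cpp_nb_loglik(IntegerVector d, NumericVector r,
                            NumericVector p) {
  const int N = d.size(), M = r.size();
  NumericMatrix out(N, M);
  int maxd = 0;
  for (int i = 0; i < N; ++i) if (d[i] > maxd) maxd = d[i];
  std::vector<double> lgd(N);
  for (int i = 0; i < N; ++i) lgd[i] = lgamma((double)d[i] + 1.0);
  std::vector<double> tab(maxd + 1);
  for (int j = 0; j < M; ++j) {
    const double rj = r[j], lp = std::log(p[j]), l1p = std::log1p(-p[j]);
    const double cj = -lgamma(rj) + rj * l1p;
    for (int v = 0; v <= maxd; ++v) tab[v] = lgamma(v + rj);
    double* col = &out(0, j);
    for (int i = 0; i < N; ++i) {
      col[i] = tab[d[i]] - lgd[i] + cj + d[i] * lp;
    }
  }
  return out;
}

// B-allele log-likelihood matrix: equal-weight mixture of Binomial(T, q_j)
// and Binomial(T, 1 - q_j) (single binomial when mirror = false)
// [[Rcpp::export]]
NumericMatrix cpp_baf_loglik(IntegerVector b, IntegerVector T,
                             NumericVector q, bool mirror) {
  const int N = b.size(), M = q.size();
  NumericMatrix out(N, M);
  std::vector<double> lch(N);
  for (int i = 0; i < N; ++i) {
    lch[i] = R::lchoose((double)T[i], (double)b[i]);
  }
  const double log2 = std::log(2.0);
  for (int j = 0; j < M; ++j) {
    const double lq = std::log(q[j]), l1q = std::log1p(-q[j]);
    double* col = &out(0, j);
    for (int i = 0; i < N; ++i) {
      const double bi = b[i], ti = T[i];
      const double l1 = lch[i] + bi * lq + (ti - bi) * l1q;
      if (!mirror) {
        col[i] = l1;
      } else {
        const double l2 = lch[i] + bi * l1q + (ti - bi) * lq;
        const double hi = l1 > l2 ? l1 : l2;
        col[i] = hi + std::log1p(std::exp(-std::fabs(l1 - l2))) - log2;
      }
    }
  }
  return out;
}

// posterior-weighted column sums of the NB log-pmf: sum_i G_ij * logNB_ij
// [[Rcpp::export]]
NumericVector cpp_nb_qcols(IntegerVector d, NumericVector r, NumericVector p,
                           NumericMatrix G) {
  const int N = d.size(), M = r.size();
  NumericVector out(M);
  int maxd = 0;
  for (int i = 0; i < N; ++i) if (d[i] > maxd) maxd = d[i];
  std::vector<double> lgd(N);
  for (int i = 0; i < N; ++i) lgd[i] = lgamma((double)d[i] + 1.0);
  std::vector<double> tab(maxd + 1);
  for (int j = 0; j < M; ++j) {
    const double rj = r[j], lp = std::log(p[j]), l1p = std::log1p(-p[j]);
    const double cj = -lgamma(rj) + rj * l1p;
    for (int v = 0; v <= maxd; ++v) tab[v] = lgamma(v + rj);
    const double* g = &G(0, j);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      acc += g[i] * (tab[d[i]] - lgd[i] + cj + d[i] * lp);
    }
    out[j] = acc;
  }
  return out;
}

// posterior-weighted column sums of d(logNB)/dr and d2(logNB)/dr2:
// cA_j = sum_i G_ij * (digamma(d_i + r_j) - digamma(r_j) + log(1 - p_j)),
// cB_j = sum_i G_ij * (trigamma(d_i + r_j) - trigamma(r_j))
// [[Rcpp::export]]
List cpp_nb_gradcols(IntegerVector d, NumericVector r, NumericVector p,
                     NumericMatrix G) {
  const int N = d.size(), M = r.size();
  NumericVector cA(M), cB(M);
  int maxd = 0;
  for (int i = 0; i < N; ++i) if (d[i] > maxd) maxd = d[i];
  std::vector<double> ta(maxd + 1), tb(maxd + 1);
  for (int j = 0; j < M; ++j) {
    const double rj = r[j];
    const double ca = -R::digamma(rj) + std::log1p(-p[j]);
    const double cb = -R::trigamma(rj);
    for (int v = 0; v <= maxd; ++v) {
      ta[v] = R::digamma(v + rj);
      tb[v] = R::trigamma(v + rj);
    }
    const double* g = &G(0, j);
    double accA = 0.0, accB = 0.0;
    for (int i = 0; i < N; ++i) {
      accA += g[i] * (ta[d[i]] + ca);
      accB += g[i] * (tb[d[i]] + cb);
    }
    cA[j] = accA;
    cB[j] = accB;
  }
  return List::create(_["cA"] = cA, _["cB"] = cB);
}

// posterior-weighted column sums of the BAF mixture log-likelihood
// [[Rcpp::export]]
NumericVector cpp_baf_qcols(IntegerVector b, IntegerVector T, NumericVector q,
                            NumericMatrix G, bool mirror) {
  const int N = b.size(), M = q.size();
  NumericVector out(M);
  std::vector<double> lch(N);
  for (int i = 0; i < N; ++i) {
    lch[i] = R::lchoose((double)T[i], (double)b[i]);
  }
  const double log2 = std::log(2.0);
  for (int j = 0; j < M; ++j) {
    const double lq = std::log(q[j]), l1q = std::log1p(-q[j]);
    const double* g = &G(0, j);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      const double bi = b[i], ti = T[i];
      const double l1 = lch[i] + bi * lq + (ti - bi) * l1q;
      double v;
      if (!mirror) {
        v = l1;
      } else {
        const double l2 = lch[i] + bi * l1q + (ti - bi) * lq;
        const double hi = l1 > l2 ? l1 : l2;
        v = hi + std::log1p(std::exp(-std::fabs(l1 - l2))) - log2;
      }
      acc += g[i] * v;
    }
    out[j] = acc;
  }
  return out;
}

// posterior-weighted column sums of the first and second derivatives of the
// BAF mixture log-likelihood with respect to q (the binomial coefficient
// cancels from the mixture weights)
// [[Rcpp::export]]
List cpp_baf_gradcols(IntegerVector b, IntegerVector T, NumericVector q,
                      NumericMatrix G, bool mirror) {
  const int N = b.size(), M = q.size();
  NumericVector c1(M), c2(M);
  for (int j = 0; j < M; ++j) {
    const double qj = q[j], q1 = 1.0 - qj;
    const double dl = std::log1p(-qj) - std::log(qj);  // log((1-q)/q)
    const double* g = &G(0, j);
    double a1 = 0.0, a2 = 0.0;
    for (int i = 0; i < N; ++i) {
      const double bi = b[i], ri = T[i] - b[i];
      const double L1 = bi / qj - ri / q1;
      const double l1pp = -bi / (qj * qj) - ri / (q1 * q1);
      if (!mirror) {
        a1 += g[i] * L1;
        a2 += g[i] * l1pp;
      } else {
        const double L2 = ri / qj - bi / q1;
        const double l2pp = -ri / (qj * qj) - bi / (q1 * q1);
        // w1 = 1 / (1 + exp(l2 - l1)), l2 - l1 = (2b - T) * log((1-q)/q)
        const double w1 = 1.0 / (1.0 + std::exp((2.0 * bi - (double)T[i]) *
                                                dl));
        const double w2 = 1.0 - w1;
        const double df = w1 * L1 + w2 * L2;
        a1 += g[i] * df;
        a2 += g[i] * (w1 * l1pp + w2 * l2pp + w1 * w2 * (L1 - L2) * (L1 - L2));
      }
    }
    c1[j] = a1;
    c2[j] = a2;
  }
  return List::create(_["c1"] = c1, _["c2"] = c2);
}

// v %*% A for the factorized kernel (symmetric, so it also serves the
// backward pass); v is a C x K matrix in state-fastest layout
static void amult(const double* v, double* out, double rho_s, double rho_c,
                  int C, int K, double* scratch) {
  const int M = C * K;
  if (C > 1) {
    const double us = (1.0 - rho_s) / (C - 1);
    const double ds = rho_s - us;
    for (int k = 0; k < K; ++k) {
      double colsum = 0.0;
      const double* vk = v + k * C;
      for (int c = 0; c < C; ++c) colsum += vk[c];
      double* sk = scratch + k * C;
      for (int c = 0; c < C; ++c) sk[c] = ds * vk[c] + us * colsum;
    }
  } else {
    std::copy(v, v + M, scratch);
  }
  if (K > 1) {
    const double uc = (1.0 - rho_c) / (K - 1);
    const double dc = rho_c - uc;
    for (int c = 0; c < C; ++c) {
      double rowsum = 0.0;
      for (int k = 0; k < K; ++k) rowsum += scratch[k * C + c];
      for (int k = 0; k < K; ++k) {
        out[k * C + c] = dc * scratch[k * C + c] + uc * rowsum;
      }
    }
  } else {
    std::copy(scratch, scratch + M, out);
  }
}

// scaled forward-backward on one chromosome chain.
// E: N x M emission log-likelihoods; rs, rc: per-transition stay
// probabilities of the state and cluster chains; pi: initial distribution.
// Returns gamma (N x M), the chain log-likelihood, and the expected stay
// probabilities of both chains at every transition. Internally all arrays
// are M x N so each time step is a contiguous column.
// [[Rcpp::export]]
List cpp_fb(NumericMatrix E, NumericVector rs, NumericVector rc,
            NumericVector pi, int C, int K) {
  const int N = E.nrow(), M = E.ncol();
  std::vector<double> W((size_t)M * N), alpha((size_t)M * N),
      betam((size_t)M * N);
  std::vector<double> cvec(N), emax(N), buf(M), scratch(M);

  for (int t = 0; t < N; ++t) {
    double mx = R_NegInf;
    for (int j = 0; j < M; ++j) {
      const double e = E(t, j);
      if (e > mx) mx = e;
    }
    emax[t] = mx;
    double* wt = &W[(size_t)t * M];
    for (int j = 0; j < M; ++j) wt[j] = std::exp(E(t, j) - mx);
  }
  // forward
  {
    const double* w0 = &W[0];
    double* a0 = &alpha[0];
    double s = 0.0;
    for (int j = 0; j < M; ++j) {
      a0[j] = pi[j] * w0[j];
      s += a0[j];
    }
    if (!(s > 0.0) || !std::isfinite(s)) {
      stop("all-zero emission row at chain position 1");
    }
    cvec[0] = s;
    for (int j = 0; j < M; ++j) a0[j] /= s;
  }
  for (int t = 1; t < N; ++t) {
    const double* ap = &alpha[(size_t)(t - 1) * M];
    const double* wt = &W[(size_t)t * M];
    double* at = &alpha[(size_t)t * M];
    amult(ap, buf.data(), rs[t - 1], rc[t - 1], C, K, scratch.data());
    double s = 0.0;
    for (int j = 0; j < M; ++j) {
      at[j] = buf[j] * wt[j];
      s += at[j];
    }
    if (!(s > 0.0) || !std::isfinite(s)) {
      stop("all-zero emission row at chain position %d", t + 1);
    }
    cvec[t] = s;
    for (int j = 0; j < M; ++j) at[j] /= s;
  }
  // backward
  {
    double* bn = &betam[(size_t)(N - 1) * M];
    for (int j = 0; j < M; ++j) bn[j] = 1.0;
  }
  for (int t = N - 2; t >= 0; --t) {
    const double* bn = &betam[(size_t)(t + 1) * M];
    const double* wn = &W[(size_t)(t + 1) * M];
    double* bt = &betam[(size_t)t * M];
    for (int j = 0; j < M; ++j) buf[j] = bn[j] * wn[j];
    std::vector<double> tmp(M);
    amult(buf.data(), tmp.data(), rs[t], rc[t], C, K, scratch.data());
    const double inv = 1.0 / cvec[t + 1];
    for (int j = 0; j < M; ++j) bt[j] = tmp[j] * inv;
  }
  // posteriors and log-likelihood
  NumericMatrix gamma(N, M);
  double ll = 0.0;
  for (int t = 0; t < N; ++t) {
    const double* at = &alpha[(size_t)t * M];
    const double* bt = &betam[(size_t)t * M];
    double rowsum = 0.0;
    for (int j = 0; j < M; ++j) {
      buf[j] = at[j] * bt[j];
      rowsum += buf[j];
    }
    for (int j = 0; j < M; ++j) gamma(t, j) = buf[j] / rowsum;
    ll += std::log(cvec[t]) + emax[t];
  }
  // expected stay probabilities per transition
  NumericVector stay_state(std::max(N - 1, 0)),
      stay_cluster(std::max(N - 1, 0));
  std::vector<double> bb(M);
  for (int t = 0; t < N - 1; ++t) {
    const double* at = &alpha[(size_t)t * M];
    const double* bn = &betam[(size_t)(t + 1) * M];
    const double* wn = &W[(size_t)(t + 1) * M];
    double T1 = 0.0, sameC = 0.0, sameK = 0.0, allS = 0.0;
    for (int j = 0; j < M; ++j) {
      bb[j] = wn[j] * bn[j];
      T1 += at[j] * bb[j];
      allS += bb[j];
    }
    for (int c = 0; c < C; ++c) {
      double sa = 0.0, sb = 0.0;
      for (int k = 0; k < K; ++k) {
        sa += at[k * C + c];
        sb += bb[k * C + c];
      }
      sameC += sa * sb;
    }
    for (int k = 0; k < K; ++k) {
      double sa = 0.0, sb = 0.0;
      const double* ak = at + k * C;
      const double* bk = bb.data() + k * C;
      for (int c = 0; c < C; ++c) {
        sa += ak[c];
        sb += bk[c];
      }
      sameK += sa * sb;
    }
    const double us = C > 1 ? (1.0 - rs[t]) / (C - 1) : 0.0;
    const double uc = K > 1 ? (1.0 - rc[t]) / (K - 1) : 0.0;
    const double z1 = rs[t] * rc[t] * T1;
    const double z2 = rs[t] * uc * (sameC - T1);
    const double z3 = us * rc[t] * (sameK - T1);
    const double z4 = us * uc * (allS - sameC - sameK + T1);
    const double Z = z1 + z2 + z3 + z4;
    stay_state[t] = C > 1 ? (z1 + z2) / Z : 1.0;
    stay_cluster[t] = K > 1 ? (z1 + z3) / Z : 1.0;
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = ll,
                      _["stay_state"] = stay_state,
                      _["stay_cluster"] = stay_cluster);
}
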