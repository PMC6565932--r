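// Block-Gibbs / collapsed Metropolis-Hastings engine for multi-subject
// precision estimation.  One sweep visits every column of every subject's
// precision matrix in random order; all randomness flows through R's RNG so
// runs are reproducible from a single seed set in R.
//
// The collapsed-evidence evaluations dominate the cost of the edge-indicator
// updates, so that path uses allocation-free kernels on pre-sized
// workspaces (manual Cholesky and triangular solves on the included subset,
// which is typically small once the network has pruned).

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::uword;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Fisher-Yates permutation driven by R's RNG
static arma::uvec randperm_r(uword n) {
  arma::uvec v = arma::regspace<arma::uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword)std::floor(unif_rand() * (double)(i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
  return v;
}

// Michael-Schucany-Haas inverse-Gaussian draw
static double rinvgauss1(double mu, double lam) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lam) -
             mu / (2.0 * lam) * std::sqrt(4.0 * mu * lam * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-300;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// ---- small dense kernels (column-major, k x k, lower triangle) ----

static bool chol_ip(double* A, int k) {
  for (int j = 0; j < k; ++j) {
    double s = A[j + j * k];
    for (int r = 0; r < j; ++r) {
      double v = A[j + r * k];
      s -= v * v;
    }
    if (s <= 0.0 || !std::isfinite(s)) return false;
    double piv = std::sqrt(s);
    A[j + j * k] = piv;
    for (int i = j + 1; i < k; ++i) {
      double t = A[i + j * k];
      for (int r = 0; r < j; ++r) t -= A[i + r * k] * A[j + r * k];
      A[i + j * k] = t / piv;
    }
  }
  return true;
}

static void fsolve_ip(const double* L, int k, double* x) {
  for (int i = 0; i < k; ++i) {
    double t = x[i];
    for (int r = 0; r < i; ++r) t -= L[i + r * k] * x[r];
    x[i] = t / L[i + i * k];
  }
}

static void bsolve_ip(const double* L, int k, double* x) {
  for (int i = k - 1; i >= 0; --i) {
    double t = x[i];
    for (int r = i + 1; r < k; ++r) t -= L[r + i * k] * x[r];
    x[i] = t / L[i + i * k];
  }
}

struct EvidWork {
  std::vector<double> Q, V, M, LM, w, m, m2;
  std::vector<const double*> Ups, b;
  void resize(int maxk, int N) {
    Q.resize((size_t)maxk * maxk);
    V.resize((size_t)maxk * maxk);
    M.resize((size_t)maxk * maxk);
    LM.resize((size_t)maxk * maxk);
    w.resize(maxk);
    m.resize(maxk);
    m2.resize(maxk);
    Ups.resize(N);
    b.resize(N);
  }
};

// Collapsed log evidence of one column's data under inclusion set `inc`.
// With `hier`, the group means of the included edges are integrated out
// under N(0, chi2) in addition to the subject strengths; the Cholesky
// factor of the mean-posterior precision M and the linear term m stay in
// W.LM / W.m for reuse by the group-mean draw.  Value is relative to the
// empty pattern (0 for k = 0).
static double col_evidence_fast(const EvidWork& cw, EvidWork& W,
                                const std::vector<int>& inc,
                                const double* d, double chi2, bool hier,
                                int pm1, int N) {
  int k = (int)inc.size();
  if (k == 0) return 0.0;
  double* Q = W.Q.data();
  double* V = W.V.data();
  double* M = W.M.data();
  double* w = W.w.data();
  double* m = W.m.data();
  double logd = 0.0;
  for (int a = 0; a < k; ++a) logd += std::log(d[inc[a]]);
  if (hier) {
    std::fill(M, M + (size_t)k * k, 0.0);
    for (int a = 0; a < k; ++a)
      M[a + a * k] = (double)N / d[inc[a]] + 1.0 / chi2;
    std::fill(m, m + k, 0.0);
  }
  double tot = 0.0;
  for (int s = 0; s < N; ++s) {
    const double* U = cw.Ups[s];
    for (int bc = 0; bc < k; ++bc) {
      const double* col = U + (size_t)pm1 * inc[bc];
      for (int a = 0; a < k; ++a) Q[a + bc * k] = col[inc[a]];
      Q[bc + bc * k] += 1.0 / d[inc[bc]];
    }
    if (!chol_ip(Q, k)) return NEG_INF;
    double logdetL = 0.0;
    for (int a = 0; a < k; ++a) logdetL += std::log(Q[a + a * k]);
    for (int a = 0; a < k; ++a) w[a] = cw.b[s][inc[a]];
    fsolve_ip(Q, k, w);
    double wq = 0.0;
    for (int a = 0; a < k; ++a) wq += w[a] * w[a];
    tot += -0.5 * logd - logdetL + 0.5 * wq;
    if (hier) {
      // V = L^{-1} diag(1/d_I): column j nonzero only in rows >= j
      for (int j = 0; j < k; ++j) {
        double* vc = V + (size_t)j * k;
        for (int a = 0; a < j; ++a) vc[a] = 0.0;
        vc[j] = (1.0 / d[inc[j]]) / Q[j + j * k];
        for (int i = j + 1; i < k; ++i) {
          double t = 0.0;
          for (int r = j; r < i; ++r) t -= Q[i + r * k] * vc[r];
          vc[i] = t / Q[i + i * k];
        }
      }
      // M -= V'V (the D^{-1} Q^{-1} D^{-1} term); m += V'w
      for (int i = 0; i < k; ++i) {
        const double* vi = V + (size_t)i * k;
        for (int j2 = i; j2 < k; ++j2) {
          const double* vj = V + (size_t)j2 * k;
          double t = 0.0;
          for (int r = j2; r < k; ++r) t += vi[r] * vj[r];
          M[i + j2 * k] -= t;
          if (j2 != i) M[j2 + i * k] = M[i + j2 * k];
        }
        double t = 0.0;
        for (int r = i; r < k; ++r) t += vi[r] * w[r];
        m[i] += t;
      }
    }
  }
  if (hier) {
    double* LM = W.LM.data();
    std::copy(M, M + (size_t)k * k, LM);
    if (!chol_ip(LM, k)) return NEG_INF;
    double logdetLM = 0.0;
    for (int a = 0; a < k; ++a) logdetLM += std::log(LM[a + a * k]);
    double* mm = W.m2.data();
    std::copy(m, m + k, mm);
    fsolve_ip(LM, k, mm);
    double mq = 0.0;
    for (int a = 0; a < k; ++a) mq += mm[a] * mm[a];
    tot += -0.5 * (double)k * std::log(chi2) - logdetLM + 0.5 * mq;
  }
  return tot;
}

// ---- incremental evidence for single-entry flips ----
//
// The indicator sweep proposes one flip at a time, so consecutive
// evaluations differ by one border row/column of every subject's Q and a
// low-rank change of the mean-posterior precision M.  The cache holds the
// factorisations of the current pattern; proposals are scored with
// O(N k^2) bordered updates instead of O(N k^3) fresh factorisations.
// During the first sweeps of every run the incremental values are checked
// against the full computation and any disagreement aborts the chain.

struct ZCache {
  int k = 0;
  int maxk = 0;
  double subj_sum = 0.0;  // sum of per-subject evidence parts
  double ev = 0.0;        // total evidence of the current pattern
  std::vector<double> L;        // N * maxk*maxk subject Cholesky factors
  std::vector<double> w;        // N * maxk, w = L^{-1} b_I
  std::vector<double> g;        // N * maxk, g = Q^{-1} b_I
  std::vector<double> logdetL;  // N
  std::vector<double> M, m;     // mean-posterior precision and linear term
  void resize(int maxk_, int N) {
    maxk = maxk_;
    L.resize((size_t)N * maxk * maxk);
    w.resize((size_t)N * maxk);
    g.resize((size_t)N * maxk);
    logdetL.resize(N);
    M.resize((size_t)maxk * maxk);
    m.resize(maxk);
  }
};

// full evidence evaluation that also fills the incremental cache
static double build_zcache(const EvidWork& cw, EvidWork& W,
                           const std::vector<int>& inc, const double* d,
                           double chi2, bool hier, int pm1, int N,
                           ZCache& C) {
  int k = (int)inc.size();
  C.k = k;
  C.subj_sum = 0.0;
  if (k == 0) {
    C.ev = 0.0;
    return 0.0;
  }
  double* M = C.M.data();
  double* m = C.m.data();
  double logd = 0.0;
  for (int a = 0; a < k; ++a) logd += std::log(d[inc[a]]);
  if (hier) {
    std::fill(M, M + (size_t)k * k, 0.0);
    for (int a = 0; a < k; ++a)
      M[a + a * k] = (double)N / d[inc[a]] + 1.0 / chi2;
    std::fill(m, m + k, 0.0);
  }
  double* V = W.V.data();
  for (int s = 0; s < N; ++s) {
    double* Q = C.L.data() + (size_t)s * C.maxk * C.maxk;
    double* w = C.w.data() + (size_t)s * C.maxk;
    double* g = C.g.data() + (size_t)s * C.maxk;
    for (int bc = 0; bc < k; ++bc) {
      const double* col = cw.Ups[s] + (size_t)pm1 * inc[bc];
      for (int a = 0; a < k; ++a) Q[a + bc * k] = col[inc[a]];
      Q[bc + bc * k] += 1.0 / d[inc[bc]];
    }
    if (!chol_ip(Q, k)) return NEG_INF;
    double logdetL = 0.0;
    for (int a = 0; a < k; ++a) logdetL += std::log(Q[a + a * k]);
    C.logdetL[s] = logdetL;
    for (int a = 0; a < k; ++a) w[a] = cw.b[s][inc[a]];
    fsolve_ip(Q, k, w);
    double wq = 0.0;
    for (int a = 0; a < k; ++a) wq += w[a] * w[a];
    C.subj_sum += -0.5 * logd - logdetL + 0.5 * wq;
    std::copy(w, w + k, g);
    bsolve_ip(Q, k, g);
    if (hier) {
      for (int j = 0; j < k; ++j) {
        double* vc = V + (size_t)j * k;
        for (int a = 0; a < j; ++a) vc[a] = 0.0;
        vc[j] = (1.0 / d[inc[j]]) / Q[j + j * k];
        for (int i = j + 1; i < k; ++i) {
          double t = 0.0;
          for (int r = j; r < i; ++r) t -= Q[i + r * k] * vc[r];
          vc[i] = t / Q[i + i * k];
        }
      }
      for (int i = 0; i < k; ++i) {
        const double* vi = V + (size_t)i * k;
        for (int j2 = i; j2 < k; ++j2) {
          const double* vj = V + (size_t)j2 * k;
          double t = 0.0;
          for (int r = j2; r < k; ++r) t += vi[r] * vj[r];
          M[i + j2 * k] -= t;
          if (j2 != i) M[j2 + i * k] = M[i + j2 * k];
        }
        double t = 0.0;
        for (int r = i; r < k; ++r) t += vi[r] * w[r];
        m[i] += t;
      }
    }
  }
  double tot = C.subj_sum;
  if (hier) {
    double* LM = W.LM.data();
    std::copy(M, M + (size_t)k * k, LM);
    if (!chol_ip(LM, k)) return NEG_INF;
    double logdetLM = 0.0;
    for (int a = 0; a < k; ++a) logdetLM += std::log(LM[a + a * k]);
    double* mm = W.m2.data();
    std::copy(m, m + k, mm);
    fsolve_ip(LM, k, mm);
    double mq = 0.0;
    for (int a = 0; a < k; ++a) mq += mm[a] * mm[a];
    tot += -0.5 * (double)k * std::log(chi2) - logdetLM + 0.5 * mq;
  }
  C.ev = tot;
  return tot;
}

// evidence of the pattern with coordinate `t` (not in inc) added
static double zcache_propose_add(const EvidWork& cw, EvidWork& W,
                                 const std::vector<int>& inc, int t,
                                 const double* d, double chi2, bool hier,
                                 int pm1, int N, const ZCache& C) {
  int k = C.k;
  int k1 = k + 1;
  double dinv_t = 1.0 / d[t];
  double* M1 = W.M.data();
  double* m1 = W.m.data();
  if (hier) {
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i)
        M1[i + j * k1] = C.M[i + j * k];
    for (int a = 0; a < k; ++a) {
      M1[a + k * k1] = 0.0;
      m1[a] = C.m[a];
    }
    M1[k + k * k1] = (double)N * dinv_t + 1.0 / chi2;
    m1[k] = 0.0;
  }
  double* l = W.w.data();
  double* vt = W.m2.data();
  double dsum = 0.0;
  for (int s = 0; s < N; ++s) {
    const double* L = C.L.data() + (size_t)s * C.maxk * C.maxk;
    const double* w = C.w.data() + (size_t)s * C.maxk;
    const double* Ucol = cw.Ups[s] + (size_t)pm1 * t;
    for (int a = 0; a < k; ++a) l[a] = Ucol[inc[a]];
    fsolve_ip(L, k, l);
    double qt = Ucol[t] + dinv_t;
    double ll = 0.0, lw = 0.0;
    for (int a = 0; a < k; ++a) {
      ll += l[a] * l[a];
      lw += l[a] * w[a];
    }
    double piv2 = qt - ll;
    if (piv2 <= 1e-300) return NEG_INF;
    double bt = cw.b[s][t];
    double wt = (bt - lw) / std::sqrt(piv2);
    dsum += -0.5 * std::log(d[t]) - 0.5 * std::log(piv2) + 0.5 * wt * wt;
    if (hier) {
      std::copy(l, l + k, vt);
      bsolve_ip(L, k, vt);  // vt = Q^{-1} q
      double alpha = 1.0 / piv2;
      for (int a = 0; a < k; ++a) {
        double ra = vt[a] / d[inc[a]];
        for (int b2 = a; b2 < k; ++b2) {
          double upd = alpha * ra * (vt[b2] / d[inc[b2]]);
          M1[a + b2 * k1] -= upd;
          if (b2 != a) M1[b2 + a * k1] = M1[a + b2 * k1];
        }
        double cross = alpha * ra * dinv_t;
        M1[a + k * k1] += cross;
        M1[k + a * k1] = M1[a + k * k1];
        m1[a] += alpha * ra * (lw - bt);
      }
      M1[k + k * k1] -= alpha * dinv_t * dinv_t;
      m1[k] += alpha * dinv_t * (bt - lw);
    }
  }
  double tot = C.subj_sum + dsum;
  if (hier) {
    double* LM = W.LM.data();
    std::copy(M1, M1 + (size_t)k1 * k1, LM);
    if (!chol_ip(LM, k1)) return NEG_INF;
    double logdetLM = 0.0;
    for (int a = 0; a < k1; ++a) logdetLM += std::log(LM[a + a * k1]);
    double* mm = W.V.data();
    std::copy(m1, m1 + k1, mm);
    fsolve_ip(LM, k1, mm);
    double mq = 0.0;
    for (int a = 0; a < k1; ++a) mq += mm[a] * mm[a];
    tot += -0.5 * (double)k1 * std::log(chi2) - logdetLM + 0.5 * mq;
  }
  return tot;
}

// evidence of the pattern with the coordinate at position `pos` removed
static double zcache_propose_remove(EvidWork& W, const std::vector<int>& inc,
                                    int pos, const double* d, double chi2,
                                    bool hier, int N, const ZCache& C) {
  int k = C.k;
  int k1 = k - 1;
  if (k1 == 0) return 0.0;  // empty pattern by convention
  double* M1 = W.M.data();
  double* m1 = W.m.data();
  if (hier) {
    for (int j = 0, jc = 0; j < k; ++j) {
      if (j == pos) continue;
      for (int i = 0, ic = 0; i < k; ++i) {
        if (i == pos) continue;
        M1[ic + jc * k1] = C.M[i + j * k];
        ++ic;
      }
      ++jc;
    }
    for (int a = 0, ac = 0; a < k; ++a) {
      if (a == pos) continue;
      m1[ac++] = C.m[a];
    }
  }
  double* c = W.w.data();
  double dsum = 0.0;
  for (int s = 0; s < N; ++s) {
    const double* L = C.L.data() + (size_t)s * C.maxk * C.maxk;
    const double* g = C.g.data() + (size_t)s * C.maxk;
    std::fill(c, c + k, 0.0);
    c[pos] = 1.0;
    fsolve_ip(L, k, c);
    bsolve_ip(L, k, c);  // c = Q^{-1} e_pos
    double gamma = c[pos];
    double gpos = g[pos];
    dsum += 0.5 * std::log(d[inc[pos]]) - 0.5 * std::log(gamma) -
            0.5 * gpos * gpos / gamma;
    if (hier) {
      double alpha = 1.0 / gamma;
      for (int a = 0, ac = 0; a < k; ++a) {
        if (a == pos) continue;
        double ra = c[a] / d[inc[a]];
        for (int b2 = a, bc = ac; b2 < k; ++b2) {
          if (b2 == pos) continue;
          double upd = alpha * ra * (c[b2] / d[inc[b2]]);
          M1[ac + bc * k1] += upd;
          if (bc != ac) M1[bc + ac * k1] = M1[ac + bc * k1];
          ++bc;
        }
        m1[ac] -= ra * gpos * alpha;
        ++ac;
      }
    }
  }
  double tot = C.subj_sum + dsum;
  if (hier) {
    double* LM = W.LM.data();
    std::copy(M1, M1 + (size_t)k1 * k1, LM);
    if (!chol_ip(LM, k1)) return NEG_INF;
    double logdetLM = 0.0;
    for (int a = 0; a < k1; ++a) logdetLM += std::log(LM[a + a * k1]);
    double* mm = W.V.data();
    std::copy(m1, m1 + k1, mm);
    fsolve_ip(LM, k1, mm);
    double mq = 0.0;
    for (int a = 0; a < k1; ++a) mq += mm[a] * mm[a];
    tot += -0.5 * (double)k1 * std::log(chi2) - logdetLM + 0.5 * mq;
  }
  return tot;
}

static arma::mat pcorr_of(const arma::mat& Om) {
  arma::vec s = arma::sqrt(Om.diag());
  arma::mat P = -Om / (s * s.t());
  P.diag().ones();
  return P;
}

// model codes: 0 strong, 1 weak, 2 single_subject, 3 bayesian_glasso, 4 ssvs
// [[Rcpp::export]]
List hp_run_chain(arma::cube S, IntegerVector n_s, int model,
                  arma::cube Omega, arma::mat mu, arma::mat sigma,
                  arma::imat Z, double chi, double a, arma::vec lambda,
                  List constants, int n_warmup, int n_samples, int thin,
                  double mh_step, bool fix_z,
                  double ssvs_v0, double ssvs_v1, double ssvs_a,
                  double bglasso_lambda, bool store_draws) {
  RNGScope scope;
  const int p = (int)S.n_rows;
  const int N = (int)S.n_slices;
  const int pm1 = p - 1;
  const bool hier = (model == 0 || model == 1);
  const bool has_z = (model == 0 || model == 2);
  const double m_sigma = constants["m_sigma"];
  const double s_sigma = constants["s_sigma"];
  const double A = constants["A"];
  const double a_pi = constants["a_pi"];
  const double b_pi = constants["b_pi"];
  const double gshape = constants["gamma_shape"];
  const double v0sq = ssvs_v0 * ssvs_v0, v1sq = ssvs_v1 * ssvs_v1;

  double chi2 = chi * chi;
  double xi = 1.0;
  if (model == 1) a = 1.0;
  if (model == 4) a = ssvs_a;

  arma::mat tau(p, p, arma::fill::ones);    // bglasso latent scales
  arma::imat rmat(p, p, arma::fill::ones);  // ssvs mixture indicators
  if (model == 1 || model == 3 || model == 4) Z.ones();
  Z.diag().zeros();

  const int n_iter = n_warmup + n_samples;
  const int n_keep = (thin > 0) ? n_samples / thin : 0;
  arma::cube pcorr_sum(p, p, N, arma::fill::zeros);
  arma::cube omega_sum(p, p, N, arma::fill::zeros);
  arma::mat edge_sum(p, p, arma::fill::zeros);
  std::vector<double> chi_draws, a_draws, loglik_draws;
  NumericVector omega_draws;
  if (store_draws && n_keep > 0) {
    omega_draws = NumericVector((R_xlen_t)p * p * N * n_keep);
    omega_draws.attr("dim") = IntegerVector::create(p, p, N, n_keep);
  }
  int kept = 0;
  long pd_failures = 0;
  long sig_att = 0, sig_acc = 0;
  long batch_att = 0, batch_acc = 0;

  // per-column working set: full (p-1)-sized quantities per subject
  std::vector<arma::mat> Ups(N), O11inv(N);
  std::vector<arma::vec> bvec(N);
  arma::vec scale22(N);
  EvidWork cw, W;
  cw.resize(pm1 > 0 ? pm1 : 1, N);
  W.resize(pm1 > 0 ? pm1 : 1, N);
  ZCache ZC;
  ZC.resize(pm1 > 0 ? pm1 : 1, N);
  std::vector<double> dcol(pm1);
  std::vector<int> z12(pm1), inc;
  inc.reserve(pm1);

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 128 == 0) Rcpp::checkUserInterrupt();
    arma::uvec cols = randperm_r(p);
    for (int jj = 0; jj < p; ++jj) {
      uword j = cols[jj];
      arma::uvec keep(pm1);
      {
        uword t = 0;
        for (uword i = 0; i < (uword)p; ++i)
          if (i != j) keep[t++] = i;
      }
      for (int s = 0; s < N; ++s) {
        arma::mat O11 = Omega.slice(s)(keep, keep);
        O11inv[s] = arma::inv_sympd(O11);
        double S22 = S(j, j, s);
        scale22[s] = S22 + lambda[s];
        Ups[s] = scale22[s] * O11inv[s];
        arma::vec S12(pm1);
        for (int t = 0; t < pm1; ++t) S12[t] = S(keep[t], j, s);
        bvec[s] = -S12;
        cw.Ups[s] = Ups[s].memptr();
        cw.b[s] = bvec[s].memptr();
      }
      for (int t = 0; t < pm1; ++t) {
        uword i = keep[t];
        switch (model) {
          case 0:
          case 1:
            dcol[t] = sigma(i, j) * sigma(i, j);
            break;
          case 2:
            dcol[t] = 0.49;  // fixed slab sd 0.7
            break;
          case 3:
            dcol[t] = tau(i, j);
            break;
          default:
            dcol[t] = rmat(i, j) ? v1sq : v0sq;
        }
        z12[t] = (model == 1 || model == 3 || model == 4) ? 1 : (int)Z(i, j);
      }
      if (has_z && !fix_z) {
        // collapsed MH over the column's edge indicators, one flip proposal
        // per entry per sweep in random order; proposals scored with the
        // incremental bordered updates, audited against the full
        // computation during the first sweeps of the run
        const bool audit = (iter < 2);
        inc.clear();
        for (int t = 0; t < pm1; ++t)
          if (z12[t]) inc.push_back(t);
        double ev = build_zcache(cw, W, inc, dcol.data(), chi2, hier, pm1,
                                 N, ZC);
        double ac = std::min(std::max(a, 1e-12), 1.0 - 1e-12);
        double la = std::log(ac), l1a = std::log1p(-ac);
        arma::uvec order = randperm_r(pm1);
        for (int tt = 0; tt < pm1; ++tt) {
          int t = (int)order[tt];
          if (a >= 1.0 - 1e-12 && z12[t] == 1) continue;
          double evp;
          std::vector<int> incp;
          incp.reserve(inc.size() + 1);
          for (int r = 0; r < pm1; ++r)
            if (r == t ? !z12[r] : z12[r]) incp.push_back(r);
          if (!z12[t]) {
            evp = (ZC.k == 0)
                      ? col_evidence_fast(cw, W, incp, dcol.data(), chi2,
                                          hier, pm1, N)
                      : zcache_propose_add(cw, W, inc, t, dcol.data(), chi2,
                                           hier, pm1, N, ZC);
          } else {
            int pos = (int)(std::lower_bound(inc.begin(), inc.end(), t) -
                            inc.begin());
            evp = zcache_propose_remove(W, inc, pos, dcol.data(), chi2,
                                        hier, N, ZC);
          }
          if (audit) {
            double full = col_evidence_fast(cw, W, incp, dcol.data(), chi2,
                                            hier, pm1, N);
            if (std::isfinite(full) &&
                std::fabs(evp - full) >
                    1e-6 * std::max(1.0, std::fabs(full))) {
              Rcpp::stop("incremental evidence update disagrees with the "
                         "full computation");
            }
          }
          double lpr = z12[t] ? (l1a - la) : (la - l1a);
          if (std::log(unif_rand()) < evp - ev + lpr) {
            z12[t] = 1 - z12[t];
            inc.swap(incp);
            ev = build_zcache(cw, W, inc, dcol.data(), chi2, hier, pm1, N,
                              ZC);
          }
        }
        for (int t = 0; t < pm1; ++t) {
          Z(keep[t], j) = z12[t];
          Z(j, keep[t]) = z12[t];
        }
      } else {
        inc.clear();
        for (int t = 0; t < pm1; ++t)
          if (z12[t]) inc.push_back(t);
      }
      int k = (int)inc.size();
      // group means of the column (hierarchical models only)
      arma::vec mu12(pm1, arma::fill::zeros);
      if (hier) {
        for (int t = 0; t < pm1; ++t) mu12[t] = std::sqrt(chi2) * norm_rand();
        if (k > 0) {
          // refresh W.LM / W.m for the current pattern, then draw
          col_evidence_fast(cw, W, inc, dcol.data(), chi2, true, pm1, N);
          std::vector<double> mm(W.m.begin(), W.m.begin() + k);
          fsolve_ip(W.LM.data(), k, mm.data());
          bsolve_ip(W.LM.data(), k, mm.data());  // mm = M^{-1} m
          std::vector<double> zr(k);
          for (int t2 = 0; t2 < k; ++t2) zr[t2] = norm_rand();
          bsolve_ip(W.LM.data(), k, zr.data());
          for (int t2 = 0; t2 < k; ++t2) mu12[inc[t2]] = mm[t2] + zr[t2];
        }
        for (int t = 0; t < pm1; ++t) {
          mu(keep[t], j) = mu12[t];
          mu(j, keep[t]) = mu12[t];
        }
      }
      // subject strengths and Schur complements
      for (int s = 0; s < N; ++s) {
        arma::vec u(pm1, arma::fill::zeros);
        if (k > 0) {
          double* Q = W.Q.data();
          for (int bc = 0; bc < k; ++bc) {
            const double* col = cw.Ups[s] + (size_t)pm1 * inc[bc];
            for (int a2 = 0; a2 < k; ++a2) Q[a2 + bc * k] = col[inc[a2]];
            Q[bc + bc * k] += 1.0 / dcol[inc[bc]];
          }
          bool ok = chol_ip(Q, k);
          if (!ok) Rcpp::stop("column update lost positive definiteness");
          std::vector<double> c(k);
          for (int t2 = 0; t2 < k; ++t2) {
            c[t2] = cw.b[s][inc[t2]];
            if (hier) c[t2] += mu12[inc[t2]] / dcol[inc[t2]];
          }
          fsolve_ip(Q, k, c.data());
          bsolve_ip(Q, k, c.data());  // c = Q^{-1} (b + D^{-1} mu)
          std::vector<double> zr(k);
          for (int t2 = 0; t2 < k; ++t2) zr[t2] = norm_rand();
          bsolve_ip(Q, k, zr.data());
          for (int t2 = 0; t2 < k; ++t2) u[inc[t2]] = c[t2] + zr[t2];
        }
        double nu = R::rgamma((double)n_s[s] / 2.0 + 1.0, 2.0 / scale22[s]);
        double o22 = nu + arma::dot(u, O11inv[s] * u);
        for (int t = 0; t < pm1; ++t) {
          Omega(keep[t], j, s) = u[t];
          Omega(j, keep[t], s) = u[t];
        }
        Omega(j, j, s) = o22;
      }
    }

    // ---- global updates over unordered pairs ----
    if (hier) {
      // between-subject scales: random-walk MH on log sigma per included edge
      for (int i = 0; i < p; ++i) {
        for (int j2 = i + 1; j2 < p; ++j2) {
          if (Z(i, j2) == 1) {
            double ls = std::log(sigma(i, j2));
            double lsp = ls + mh_step * norm_rand();
            double lp0 = R::dnorm(ls, std::log(m_sigma), s_sigma, 1);
            double lp1 = R::dnorm(lsp, std::log(m_sigma), s_sigma, 1);
            double s0 = std::exp(ls), s1 = std::exp(lsp);
            for (int s = 0; s < N; ++s) {
              double om = Omega(i, j2, s);
              lp0 += R::dnorm(om, mu(i, j2), s0, 1);
              lp1 += R::dnorm(om, mu(i, j2), s1, 1);
            }
            ++sig_att;
            ++batch_att;
            if (std::log(unif_rand()) < lp1 - lp0) {
              sigma(i, j2) = s1;
              sigma(j2, i) = s1;
              ++sig_acc;
              ++batch_acc;
            }
          } else {
            double s1 = std::exp(std::log(m_sigma) + s_sigma * norm_rand());
            sigma(i, j2) = s1;
            sigma(j2, i) = s1;
          }
        }
      }
      // adapt the proposal scale towards 40% acceptance during warm-up
      if (iter < n_warmup && batch_att >= 200) {
        double rate = (double)batch_acc / (double)batch_att;
        mh_step *= std::exp(rate - 0.4);
        mh_step = std::min(std::max(mh_step, 1e-3), 5.0);
        batch_att = 0;
        batch_acc = 0;
      }
      // global scale chi via the inverse-gamma expansion
      double ss = 0.0, E = 0.0;
      for (int i = 0; i < p; ++i)
        for (int j2 = i + 1; j2 < p; ++j2) {
          ss += mu(i, j2) * mu(i, j2);
          E += 1.0;
        }
      chi2 = 1.0 / R::rgamma((E + 1.0) / 2.0, 1.0 / (1.0 / xi + ss / 2.0));
      xi = 1.0 / R::rgamma(1.0, 1.0 / (1.0 / (A * A) + 1.0 / chi2));
    }
    if (model == 0 || model == 2) {
      double on = 0.0, off = 0.0;
      for (int i = 0; i < p; ++i)
        for (int j2 = i + 1; j2 < p; ++j2)
          (Z(i, j2) == 1 ? on : off) += 1.0;
      a = R::rbeta(a_pi + on, b_pi + off);
    }
    if (model == 3) {
      // latent Laplace scales: 1/tau | omega ~ InvGauss(lam/|omega|, lam^2)
      for (int i = 0; i < p; ++i)
        for (int j2 = i + 1; j2 < p; ++j2) {
          double om = std::fabs(Omega(i, j2, 0));
          if (om < 1e-10) om = 1e-10;
          double inv_tau = rinvgauss1(bglasso_lambda / om,
                                      bglasso_lambda * bglasso_lambda);
          double t1 = 1.0 / inv_tau;
          tau(i, j2) = t1;
          tau(j2, i) = t1;
        }
    }
    if (model == 4) {
      // mixture indicators given current entries
      for (int i = 0; i < p; ++i)
        for (int j2 = i + 1; j2 < p; ++j2) {
          double om = Omega(i, j2, 0);
          double l1 = std::log(ssvs_a) + R::dnorm(om, 0.0, ssvs_v1, 1);
          double l0 = std::log(1.0 - ssvs_a) + R::dnorm(om, 0.0, ssvs_v0, 1);
          double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
          int r1 = (unif_rand() < p1) ? 1 : 0;
          rmat(i, j2) = r1;
          rmat(j2, i) = r1;
        }
    }
    // diagonal rates
    for (int s = 0; s < N; ++s) {
      double tr = arma::accu(Omega.slice(s).diag());
      lambda[s] = R::rgamma(gshape + (double)p, 2.0 / tr);
    }

    // ---- record ----
    if (iter >= n_warmup && thin > 0 && (iter - n_warmup) % thin == thin - 1) {
      double ll = 0.0;
      for (int s = 0; s < N; ++s) {
        arma::mat L;
        bool ok = arma::chol(L, Omega.slice(s), "lower");
        if (!ok || L.diag().min() <= 1e-10) {
          ++pd_failures;
        } else {
          ll += (double)n_s[s] * arma::accu(arma::log(L.diag())) -
                0.5 * arma::accu(S.slice(s) % Omega.slice(s));
        }
        pcorr_sum.slice(s) += pcorr_of(Omega.slice(s));
        omega_sum.slice(s) += Omega.slice(s);
      }
      if (model == 0 || model == 2) {
        edge_sum += arma::conv_to<arma::mat>::from(Z);
      } else if (model == 4) {
        edge_sum += arma::conv_to<arma::mat>::from(rmat);
      }
      if (hier) chi_draws.push_back(std::sqrt(chi2));
      if (model == 0 || model == 2) a_draws.push_back(a);
      loglik_draws.push_back(ll);
      if (store_draws && kept < n_keep) {
        std::copy(Omega.begin(), Omega.end(),
                  omega_draws.begin() + (R_xlen_t)kept * p * p * N);
      }
      ++kept;
    }
  }

  double denom = (double)std::max(kept, 1);
  arma::cube pcorr_mean = pcorr_sum / denom;
  arma::cube omega_mean = omega_sum / denom;
  arma::mat group_pcorr(p, p, arma::fill::zeros);
  for (int s = 0; s < N; ++s) group_pcorr += pcorr_mean.slice(s);
  group_pcorr /= (double)N;
  arma::mat edge_prob = edge_sum / denom;

  List out = List::create(
      _["pcorr_mean"] = pcorr_mean, _["group_pcorr_mean"] = group_pcorr,
      _["omega_mean"] = omega_mean, _["edge_prob"] = edge_prob,
      _["chi_draws"] = chi_draws, _["a_draws"] = a_draws,
      _["loglik_draws"] = loglik_draws,
      _["sigma_accept"] = sig_att > 0 ? (double)sig_acc / (double)sig_att
                                      : NA_REAL,
      _["mh_step"] = mh_step, _["pd_failures"] = (double)pd_failures,
      _["n_kept"] = kept);
  if (store_draws && n_keep > 0) out["omega_draws"] = omega_draws;
  return out;
}
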