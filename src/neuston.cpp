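// Core numerics: bivariate compound Poisson log-pmf for dual-observer
// counts, an adaptive Metropolis-within-Gibbs sampler for the hierarchical
// model, and the marginal site likelihood used by leave-one-out
// cross-validation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// growable table of log k! (single-threaded use under the R interpreter)
static std::vector<double> lgf(1, 0.0);
static inline double lgfact(int k) {
  while ((int)lgf.size() <= k) {
    lgf.push_back(lgf.back() + std::log((double)lgf.size()));
  }
  return lgf[k];
}

// log P(Y1=y1, Y2=y2) where Y1 = U1 + W, Y2 = U2 + W with
// U1, U2 ~ Poisson(lam*p*(1-p)) and W ~ Poisson(lam*p^2) independent:
// the joint law of two independent binomial-p thinnings of one latent
// Poisson(lam) count.  Computed in log space via the finite sum over the
// shared component k = 0..min(y1, y2).
static double dual_logpmf_one(int y1, int y2, double lam, double p) {
  if (y1 < 0 || y2 < 0) return R_NegInf;
  if (lam <= 0.0) return (y1 == 0 && y2 == 0 && lam == 0.0) ? 0.0 : R_NegInf;
  if (p >= 1.0) return (y1 == y2) ? R::dpois(y1, lam, 1) : R_NegInf;
  const double l1 = lam * p * (1.0 - p);   // observer-specific components
  const double l2 = lam * p * p;           // shared component
  const double logl1 = std::log(l1), logl2 = std::log(l2);
  const double base = -(l2 + 2.0 * l1);
  const int m = y1 < y2 ? y1 : y2;
  double mx = R_NegInf;
  std::vector<double> terms(m + 1);
  for (int k = 0; k <= m; ++k) {
    double t = base + k * logl2 - lgfact(k)
             + (y1 - k) * logl1 - lgfact(y1 - k)
             + (y2 - k) * logl1 - lgfact(y2 - k);
    terms[k] = t;
    if (t > mx) mx = t;
  }
  if (!R_FINITE(mx)) return R_NegInf;
  double s = 0.0;
  for (int k = 0; k <= m; ++k) s += std::exp(terms[k] - mx);
  return mx + std::log(s);
}

// [[Rcpp::export]]
NumericVector dual_logpmf_cpp(IntegerVector y1, IntegerVector y2,
                              NumericVector lam, NumericVector p) {
  int n = y1.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = dual_logpmf_one(y1[i], y2[i], lam[i], p[i]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sampler
// ---------------------------------------------------------------------------

// The model, in the unconstrained parametrization sampled here:
//   beta    J x P regression coefficients (normal priors)
//   log_tau J log random-effect scales (half-normal on tau)
//   y_z     J(J-1)/2 unconstrained canonical partial correlations giving the
//           Cholesky factor L of the correlation matrix Omega (LKJ prior)
//   logit_p J logit detection probabilities (beta priors); dual model only
//   U       n x J: non-centered standard-normal effects (eps = tau * (L u)),
//           or the effects themselves when `centered`
// Likelihood: per site i and category j, lambda_ij = A_i exp(X_i beta_j +
// eps_ij); dual-observer compound Poisson or single-count Poisson.
//
// Updates per sweep: per-site random-walk blocks on U rows; componentwise
// random walks on beta, logit p, log tau and the correlation coordinates;
// and one covariance-adaptive block per category jointly moving
// (beta_j, logit p_j, log tau_j), which handles the strong posterior
// correlations (intercept vs detectability, slope vs intercept) that
// componentwise moves cannot follow.  All proposal scales and the block
// covariances adapt during warmup only.

struct Chain {
  int n, J, P, M;             // M = J(J-1)/2
  int likelihood;             // 0 dual, 1 single-count Poisson
  bool centered;
  NumericMatrix X;            // n x P
  NumericVector A;            // n
  IntegerMatrix Y1, Y2;       // n x J
  NumericMatrix beta_loc, beta_scale;  // J x P
  NumericVector tau_scale;    // J
  double lkj_eta;
  NumericVector p_a, p_b;     // J

  NumericMatrix beta;         // J x P
  NumericVector log_tau;      // J
  NumericVector y_z;          // M, row-major rows 1..J-1
  NumericVector logit_p;      // J
  NumericMatrix U;            // n x J

  NumericVector tau, p;       // J
  NumericMatrix L;            // J x J lower Cholesky of Omega
  NumericMatrix Xb;           // n x J  (X beta_j)
  NumericMatrix eps;          // n x J  actual random effects
  NumericMatrix ll;           // n x J  per-cell log likelihood

  int zoff(int k) const { return k * (k - 1) / 2; }

  double cell_ll(int i, int j) const {
    double lam = A[i] * std::exp(Xb(i, j) + eps(i, j));
    if (!R_FINITE(lam)) return R_NegInf;
    if (likelihood == 0)
      return dual_logpmf_one(Y1(i, j), Y2(i, j), lam, p[j]);
    return R::dpois(Y1(i, j), lam, 1);
  }

  void rebuild_L_row(int k) {
    if (k == 0) { L(0, 0) = 1.0; return; }
    double rem = 1.0;
    for (int j = 0; j < k; ++j) {
      double z = std::tanh(y_z[zoff(k) + j]);
      L(k, j) = z * std::sqrt(rem);
      rem *= (1.0 - z * z);
    }
    for (int j = k + 1; j < J; ++j) L(k, j) = 0.0;
    L(k, k) = std::sqrt(rem);
  }

  // log prior of row k of the correlation Cholesky factor in unconstrained
  // coordinates: LKJ term plus transform Jacobian (both row-local).
  double lp_z_row(int k) const {
    if (k == 0) return 0.0;
    double rem = 1.0, out = 0.0;
    for (int j = 0; j < k; ++j) {
      double z = std::tanh(y_z[zoff(k) + j]);
      out += 0.5 * std::log(rem) + std::log1p(-z * z);
      rem *= (1.0 - z * z);
    }
    double alpha = (double)(J - (k + 1)) + 2.0 * lkj_eta - 2.0;
    out += 0.5 * alpha * std::log(rem);
    return out;
  }

  double lp_beta_one(int j, int c) const {
    return R::dnorm(beta(j, c), beta_loc(j, c), beta_scale(j, c), 1);
  }
  double lp_beta_row(int j) const {
    double s = 0.0;
    for (int c = 0; c < P; ++c) s += lp_beta_one(j, c);
    return s;
  }
  double lp_tau_one(int j) const {
    double t = std::exp(log_tau[j]);
    double s = tau_scale[j];
    return -0.5 * (t / s) * (t / s) + log_tau[j];  // half-normal + Jacobian
  }
  double lp_p_one(int j) const {
    double pj = p[j];
    return p_a[j] * std::log(pj) + p_b[j] * std::log(1.0 - pj);
  }

  void refresh_Xb_col(int j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < P; ++c) s += X(i, c) * beta(j, c);
      Xb(i, j) = s;
    }
  }
  void refresh_eps_col(int j) {
    for (int i = 0; i < n; ++i) {
      if (centered) { eps(i, j) = U(i, j); continue; }
      double s = 0.0;
      for (int m = 0; m <= j; ++m) s += L(j, m) * U(i, m);
      eps(i, j) = tau[j] * s;
    }
  }
  void refresh_ll_col(int j) {
    for (int i = 0; i < n; ++i) ll(i, j) = cell_ll(i, j);
  }

  double lp_eps_centered() const {
    double logdet = 0.0;
    for (int j = 0; j < J; ++j) logdet += std::log(tau[j]) + std::log(L(j, j));
    double qf = 0.0;
    std::vector<double> v(J);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < J; ++j) {
        double s = eps(i, j) / tau[j];
        for (int m = 0; m < j; ++m) s -= L(j, m) * v[m];
        v[j] = s / L(j, j);
        qf += v[j] * v[j];
      }
    }
    return -(double)n * logdet - 0.5 * qf;
  }

  double site_qf_centered(int i) const {
    std::vector<double> v(J);
    double qf = 0.0;
    for (int j = 0; j < J; ++j) {
      double s = eps(i, j) / tau[j];
      for (int m = 0; m < j; ++m) s -= L(j, m) * v[m];
      v[j] = s / L(j, j);
      qf += v[j] * v[j];
    }
    return -0.5 * qf;
  }

  double lp_U_row_noncentered(int i) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += U(i, j) * U(i, j);
    return -0.5 * s;
  }

  double site_ll(int i) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += ll(i, j);
    return s;
  }
  double col_ll(int j) const {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += ll(i, j);
    return s;
  }

  double total_lp() const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) {
      s += lp_beta_row(j) + lp_tau_one(j) + lp_z_row(j) + col_ll(j);
      if (likelihood == 0) s += lp_p_one(j);
    }
    if (centered) {
      s += lp_eps_centered();
    } else {
      for (int i = 0; i < n; ++i) s += lp_U_row_noncentered(i);
    }
    return s;
  }
};

struct Adapt {
  std::vector<double> log_s;
  std::vector<int> t;
  double target;
  void init(int nblocks, double s0, double tgt) {
    log_s.assign(nblocks, std::log(s0));
    t.assign(nblocks, 0);
    target = tgt;
  }
  double scale(int b) const { return std::exp(log_s[b]); }
  void update(int b, double acc, bool adapting) {
    if (!adapting) return;
    t[b] += 1;
    double gamma = std::pow((double)t[b], -0.6);
    log_s[b] += gamma * (acc - target);
    if (log_s[b] < -12.0) log_s[b] = -12.0;
    if (log_s[b] > 6.0) log_s[b] = 6.0;
  }
};

// Running mean / covariance of one category's joint block (Welford)
struct BlockStats {
  int D = 0;
  long t = 0;
  std::vector<double> mean, cacc;   // D, D*D
  void init(int d) { D = d; t = 0; mean.assign(d, 0.0); cacc.assign(d * d, 0.0); }
  void push(const std::vector<double>& x) {
    t += 1;
    std::vector<double> d0(D);
    for (int a = 0; a < D; ++a) d0[a] = x[a] - mean[a];
    for (int a = 0; a < D; ++a) mean[a] += d0[a] / (double)t;
    for (int a = 0; a < D; ++a)
      for (int b = 0; b < D; ++b)
        cacc[a * D + b] += d0[a] * (x[b] - mean[b]);
  }
  // lower Cholesky of cov + ridge; false until enough samples
  bool chol(std::vector<double>& Lc) const {
    if (t < 10 * D) return false;
    std::vector<double> C(D * D);
    for (int a = 0; a < D * D; ++a) C[a] = cacc[a] / (double)(t - 1);
    for (int a = 0; a < D; ++a) C[a * D + a] += 1e-8;
    Lc.assign(D * D, 0.0);
    for (int a = 0; a < D; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = C[a * D + b];
        for (int q = 0; q < b; ++q) s -= Lc[a * D + q] * Lc[b * D + q];
        if (a == b) {
          if (s <= 0.0) return false;
          Lc[a * D + a] = std::sqrt(s);
        } else {
          Lc[a * D + b] = s / Lc[b * D + b];
        }
      }
    }
    return true;
  }
};

// [[Rcpp::export]]
List mcmc_chain_cpp(NumericMatrix X, NumericVector A,
                    IntegerMatrix Y1, IntegerMatrix Y2,
                    int likelihood, bool centered,
                    NumericMatrix beta_loc, NumericMatrix beta_scale,
                    NumericVector tau_scale, double lkj_eta,
                    NumericVector p_a, NumericVector p_b,
                    int n_warmup, int n_iter, int thin, bool save_eps,
                    List init) {
  Chain ch;
  ch.n = Y1.nrow(); ch.J = Y1.ncol(); ch.P = X.ncol();
  ch.M = ch.J * (ch.J - 1) / 2;
  ch.likelihood = likelihood; ch.centered = centered;
  ch.X = X; ch.A = A; ch.Y1 = Y1; ch.Y2 = Y2;
  ch.beta_loc = beta_loc; ch.beta_scale = beta_scale;
  ch.tau_scale = tau_scale; ch.lkj_eta = lkj_eta;
  ch.p_a = p_a; ch.p_b = p_b;

  ch.beta = clone(as<NumericMatrix>(init["beta"]));
  ch.log_tau = clone(as<NumericVector>(init["log_tau"]));
  ch.y_z = clone(as<NumericVector>(init["y_z"]));
  ch.logit_p = clone(as<NumericVector>(init["logit_p"]));
  ch.U = clone(as<NumericMatrix>(init["U"]));

  const int n = ch.n, J = ch.J, P = ch.P;
  const bool dual = (likelihood == 0);
  ch.tau = NumericVector(J); ch.p = NumericVector(J);
  ch.L = NumericMatrix(J, J);
  ch.Xb = NumericMatrix(n, J);
  ch.eps = NumericMatrix(n, J);
  ch.ll = NumericMatrix(n, J);
  for (int j = 0; j < J; ++j) {
    ch.tau[j] = std::exp(ch.log_tau[j]);
    ch.p[j] = 1.0 / (1.0 + std::exp(-ch.logit_p[j]));
    ch.rebuild_L_row(j);
  }
  for (int j = 0; j < J; ++j) {
    ch.refresh_Xb_col(j);
    ch.refresh_eps_col(j);
    ch.refresh_ll_col(j);
  }

  Adapt ad_eps, ad_beta, ad_p, ad_tau, ad_z, ad_blk, ad_shear, ad_tau_c,
        ad_z_c, ad_pridge;
  ad_eps.init(n, 0.5, 0.25);
  ad_beta.init(J * P, 0.2, 0.44);
  ad_p.init(J, 0.5, 0.44);
  ad_tau.init(J, 0.3, 0.44);
  ad_z.init(ch.M, 0.5, 0.44);
  ad_blk.init(J, 0.6, 0.30);
  ad_shear.init(J, 0.5, 0.30);
  ad_tau_c.init(J, 0.3, 0.44);
  ad_z_c.init(ch.M, 0.5, 0.44);
  ad_pridge.init(J, 0.5, 0.44);

  const int D = P + 1 + (dual ? 1 : 0);   // beta_j, log_tau_j (, logit_p_j)
  std::vector<BlockStats> bs(J);
  for (int j = 0; j < J; ++j) bs[j].init(D);
  std::vector<double> theta(D), theta_old(D), zprop(D), Lc;

  const int n_keep = n_iter / thin;
  const int n_par = J * P + J + ch.M + (dual ? J : 0) +
                    (save_eps ? n * J : 0) + 1;
  NumericMatrix draws(n_keep, n_par);
  std::vector<double> acc_count(9, 0.0), prop_count(9, 0.0);

  RNGScope scope;
  int keep = 0;
  std::vector<double> old_row(J), old_eps_r(J), old_ll_r(J);
  std::vector<double> oll(n), oXb(n), oeps(n), oL(J), oU(n * J);
  std::vector<double> zsh(P), dsh(P);
  // Cholesky of X'X + ridge, for the shear proposal geometry
  std::vector<double> Lxx(P * P, 0.0);
  {
    std::vector<double> XtX(P * P, 0.0);
    double tr = 0.0;
    for (int a = 0; a < P; ++a)
      for (int b = 0; b <= a; ++b) {
        double t = 0.0;
        for (int i = 0; i < n; ++i) t += X(i, a) * X(i, b);
        XtX[a * P + b] = XtX[b * P + a] = t;
        if (a == b) tr += t;
      }
    for (int a = 0; a < P; ++a) XtX[a * P + a] += 1e-8 * (tr > 0 ? tr : 1.0);
    for (int a = 0; a < P; ++a) {
      for (int b = 0; b <= a; ++b) {
        double t = XtX[a * P + b];
        for (int q = 0; q < b; ++q) t -= Lxx[a * P + q] * Lxx[b * P + q];
        if (a == b) Lxx[a * P + a] = std::sqrt(t > 0 ? t : 1e-12);
        else Lxx[a * P + b] = t / Lxx[b * P + b];
      }
    }
  }

  for (int iter = 0; iter < n_warmup + n_iter; ++iter) {
    bool adapting = iter < n_warmup;

    // --- site blocks: U rows ------------------------------------------------
    for (int i = 0; i < n; ++i) {
      double s = ad_eps.scale(i);
      for (int j = 0; j < J; ++j) {
        old_row[j] = ch.U(i, j);
        old_eps_r[j] = ch.eps(i, j);
        old_ll_r[j] = ch.ll(i, j);
      }
      double lp0 = ch.site_ll(i) +
        (centered ? ch.site_qf_centered(i) : ch.lp_U_row_noncentered(i));
      for (int j = 0; j < J; ++j) ch.U(i, j) += s * norm_rand();
      if (centered) {
        for (int j = 0; j < J; ++j) ch.eps(i, j) = ch.U(i, j);
      } else {
        for (int j = 0; j < J; ++j) {
          double t = 0.0;
          for (int m = 0; m <= j; ++m) t += ch.L(j, m) * ch.U(i, m);
          ch.eps(i, j) = ch.tau[j] * t;
        }
      }
      for (int j = 0; j < J; ++j) ch.ll(i, j) = ch.cell_ll(i, j);
      double lp1 = ch.site_ll(i) +
        (centered ? ch.site_qf_centered(i) : ch.lp_U_row_noncentered(i));
      double d = lp1 - lp0;
      bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
      prop_count[0] += 1;
      if (accept) {
        acc_count[0] += 1;
      } else {
        for (int j = 0; j < J; ++j) {
          ch.U(i, j) = old_row[j];
          ch.eps(i, j) = old_eps_r[j];
          ch.ll(i, j) = old_ll_r[j];
        }
      }
      ad_eps.update(i, accept ? 1.0 : 0.0, adapting);
    }

    // --- componentwise beta -------------------------------------------------
    for (int j = 0; j < J; ++j) {
      for (int c = 0; c < P; ++c) {
        int b = j * P + c;
        double s = ad_beta.scale(b);
        double old = ch.beta(j, c);
        double step = s * norm_rand();
        double lp0 = ch.col_ll(j) + ch.lp_beta_one(j, c);
        for (int i = 0; i < n; ++i) { oll[i] = ch.ll(i, j); oXb[i] = ch.Xb(i, j); }
        ch.beta(j, c) = old + step;
        for (int i = 0; i < n; ++i) ch.Xb(i, j) += X(i, c) * step;
        ch.refresh_ll_col(j);
        double lp1 = ch.col_ll(j) + ch.lp_beta_one(j, c);
        double d = lp1 - lp0;
        bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
        prop_count[1] += 1;
        if (accept) {
          acc_count[1] += 1;
        } else {
          ch.beta(j, c) = old;
          for (int i = 0; i < n; ++i) { ch.ll(i, j) = oll[i]; ch.Xb(i, j) = oXb[i]; }
        }
        ad_beta.update(b, accept ? 1.0 : 0.0, adapting);
      }
    }

    // --- detection probabilities (dual model) -------------------------------
    if (dual) {
      for (int j = 0; j < J; ++j) {
        double s = ad_p.scale(j);
        double old = ch.logit_p[j], oldp = ch.p[j];
        for (int i = 0; i < n; ++i) oll[i] = ch.ll(i, j);
        double lp0 = ch.col_ll(j) + ch.lp_p_one(j);
        ch.logit_p[j] = old + s * norm_rand();
        ch.p[j] = 1.0 / (1.0 + std::exp(-ch.logit_p[j]));
        ch.refresh_ll_col(j);
        double lp1 = ch.col_ll(j) + ch.lp_p_one(j);
        double d = lp1 - lp0;
        bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
        prop_count[2] += 1;
        if (accept) {
          acc_count[2] += 1;
        } else {
          ch.logit_p[j] = old; ch.p[j] = oldp;
          for (int i = 0; i < n; ++i) ch.ll(i, j) = oll[i];
        }
        ad_p.update(j, accept ? 1.0 : 0.0, adapting);
      }
    }

    // --- tau ----------------------------------------------------------------
    for (int j = 0; j < J; ++j) {
      double s = ad_tau.scale(j);
      double old = ch.log_tau[j], oldt = ch.tau[j];
      double lp0 = ch.lp_tau_one(j);
      if (ch.centered) lp0 += ch.lp_eps_centered();
      else {
        lp0 += ch.col_ll(j);
        for (int i = 0; i < n; ++i) { oll[i] = ch.ll(i, j); oeps[i] = ch.eps(i, j); }
      }
      ch.log_tau[j] = old + s * norm_rand();
      ch.tau[j] = std::exp(ch.log_tau[j]);
      if (!ch.centered) { ch.refresh_eps_col(j); ch.refresh_ll_col(j); }
      double lp1 = ch.lp_tau_one(j);
      if (ch.centered) lp1 += ch.lp_eps_centered();
      else lp1 += ch.col_ll(j);
      double d = lp1 - lp0;
      bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
      prop_count[3] += 1;
      if (accept) {
        acc_count[3] += 1;
      } else {
        ch.log_tau[j] = old; ch.tau[j] = oldt;
        if (!ch.centered)
          for (int i = 0; i < n; ++i) { ch.ll(i, j) = oll[i]; ch.eps(i, j) = oeps[i]; }
      }
      ad_tau.update(j, accept ? 1.0 : 0.0, adapting);
    }

    // --- correlation Cholesky rows ------------------------------------------
    // y_z[(k, m)] only enters row k of L, hence category k's effects.
    for (int k = 1; k < J; ++k) {
      for (int m = 0; m < k; ++m) {
        int b = ch.zoff(k) + m;
        double s = ad_z.scale(b);
        double old = ch.y_z[b];
        for (int j = 0; j <= k; ++j) oL[j] = ch.L(k, j);
        double lp0 = ch.lp_z_row(k);
        if (ch.centered) lp0 += ch.lp_eps_centered();
        else {
          lp0 += ch.col_ll(k);
          for (int i = 0; i < n; ++i) { oll[i] = ch.ll(i, k); oeps[i] = ch.eps(i, k); }
        }
        ch.y_z[b] = old + s * norm_rand();
        ch.rebuild_L_row(k);
        if (!ch.centered) { ch.refresh_eps_col(k); ch.refresh_ll_col(k); }
        double lp1 = ch.lp_z_row(k);
        if (ch.centered) lp1 += ch.lp_eps_centered();
        else lp1 += ch.col_ll(k);
        double d = lp1 - lp0;
        bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
        prop_count[4] += 1;
        if (accept) {
          acc_count[4] += 1;
        } else {
          ch.y_z[b] = old;
          for (int j = 0; j <= k; ++j) ch.L(k, j) = oL[j];
          if (!ch.centered)
            for (int i = 0; i < n; ++i) { ch.ll(i, k) = oll[i]; ch.eps(i, k) = oeps[i]; }
        }
        ad_z.update(b, accept ? 1.0 : 0.0, adapting);
      }
    }

    // --- interweaved (centered-coordinate) tau and correlation updates ------
    // With sharp likelihoods the effects eps are pinned by the data, so
    // non-centered moves of tau or the correlation coordinates (which drag
    // eps along) stall.  Here tau and y_z are updated holding eps fixed:
    // the likelihood cancels and the acceptance ratio involves only the
    // half-normal/LKJ priors and the MVN density of eps.  Afterwards U is
    // recomputed so the non-centered coordinates stay consistent.
    if (!centered) {
      bool moved = false;
      for (int j = 0; j < J; ++j) {
        double s = ad_tau_c.scale(j);
        double old = ch.log_tau[j], oldt = ch.tau[j];
        double lp0 = ch.lp_tau_one(j) + ch.lp_eps_centered();
        ch.log_tau[j] = old + s * norm_rand();
        ch.tau[j] = std::exp(ch.log_tau[j]);
        double lp1 = ch.lp_tau_one(j) + ch.lp_eps_centered();
        double d = lp1 - lp0;
        bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
        prop_count[7] += 1;
        if (accept) { acc_count[7] += 1; moved = true; }
        else { ch.log_tau[j] = old; ch.tau[j] = oldt; }
        ad_tau_c.update(j, accept ? 1.0 : 0.0, adapting);
      }
      for (int k = 1; k < J; ++k) {
        for (int m = 0; m < k; ++m) {
          int b = ch.zoff(k) + m;
          double s = ad_z_c.scale(b);
          double old = ch.y_z[b];
          for (int j = 0; j <= k; ++j) oL[j] = ch.L(k, j);
          double lp0 = ch.lp_z_row(k) + ch.lp_eps_centered();
          ch.y_z[b] = old + s * norm_rand();
          ch.rebuild_L_row(k);
          double lp1 = ch.lp_z_row(k) + ch.lp_eps_centered();
          double d = lp1 - lp0;
          bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
          prop_count[7] += 1;
          if (accept) { acc_count[7] += 1; moved = true; }
          else {
            ch.y_z[b] = old;
            for (int j = 0; j <= k; ++j) ch.L(k, j) = oL[j];
          }
          ad_z_c.update(b, accept ? 1.0 : 0.0, adapting);
        }
      }
      if (moved) {
        // U = L^{-1} (eps / tau), per site
        for (int i = 0; i < n; ++i) {
          for (int j2 = 0; j2 < J; ++j2) {
            double s2 = ch.eps(i, j2) / ch.tau[j2];
            for (int q = 0; q < j2; ++q) s2 -= ch.L(j2, q) * ch.U(i, q);
            ch.U(i, j2) = s2 / ch.L(j2, j2);
          }
        }
      }
    }

    // --- likelihood-invariant shear moves -----------------------------------
    // Shift the whole coefficient row beta_j by a vector delta and
    // counter-shift category j's random effects by -X delta, leaving every
    // linear predictor (hence the whole likelihood) unchanged.  Conditional
    // on tau and L this is a translation in (beta, U) space, so the
    // proposal is symmetric and the acceptance ratio involves only the
    // priors.  delta is drawn with covariance (X'X)^-1, the metric induced
    // on beta by the random-effect penalty, so the move follows the
    // collinearity ridges of the design.  These moves decouple the
    // coefficients from random effects pinned by sharp likelihoods.
    for (int j = 0; j < J; ++j) {
      double s = ad_shear.scale(j);
      for (int c = 0; c < P; ++c) zsh[c] = norm_rand();
      // delta = s * Lxx^{-T} z  (back substitution)
      for (int c = P - 1; c >= 0; --c) {
        double t = zsh[c];
        for (int q = c + 1; q < P; ++q) t -= Lxx[q * P + c] * dsh[q];
        dsh[c] = t / Lxx[c * P + c];
      }
      for (int c = 0; c < P; ++c) dsh[c] *= s;

      double lp0 = ch.lp_beta_row(j);
      if (ch.centered) {
        lp0 += ch.lp_eps_centered();
      } else {
        double pr0 = 0.0;
        for (int i = 0; i < n; ++i)
          for (int m = j; m < J; ++m) pr0 += ch.U(i, m) * ch.U(i, m);
        lp0 += -0.5 * pr0;
      }
      for (int i = 0; i < n; ++i) {
        oeps[i] = ch.eps(i, j); oXb[i] = ch.Xb(i, j);
        if (!ch.centered)
          for (int m = j; m < J; ++m) oU[i * J + m] = ch.U(i, m);
      }
      for (int c = 0; c < P; ++c) ch.beta(j, c) += dsh[c];
      for (int i = 0; i < n; ++i) {
        double xd = 0.0;
        for (int c = 0; c < P; ++c) xd += X(i, c) * dsh[c];
        ch.eps(i, j) -= xd;
        ch.Xb(i, j) += xd;
        if (ch.centered) {
          ch.U(i, j) = ch.eps(i, j);
        } else {
          for (int m = j; m < J; ++m) {
            double s2 = ch.eps(i, m) / ch.tau[m];
            for (int q = 0; q < m; ++q) s2 -= ch.L(m, q) * ch.U(i, q);
            ch.U(i, m) = s2 / ch.L(m, m);
          }
        }
      }
      double lp1 = ch.lp_beta_row(j);
      if (ch.centered) {
        lp1 += ch.lp_eps_centered();
      } else {
        double pr1 = 0.0;
        for (int i = 0; i < n; ++i)
          for (int m = j; m < J; ++m) pr1 += ch.U(i, m) * ch.U(i, m);
        lp1 += -0.5 * pr1;
      }
      double d = lp1 - lp0;
      bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
      prop_count[6] += 1;
      if (accept) {
        acc_count[6] += 1;
      } else {
        for (int c = 0; c < P; ++c) ch.beta(j, c) -= dsh[c];
        for (int i = 0; i < n; ++i) {
          ch.eps(i, j) = oeps[i];
          ch.Xb(i, j) = oXb[i];
          if (ch.centered) ch.U(i, j) = oeps[i];
          else for (int m = j; m < J; ++m) ch.U(i, m) = oU[i * J + m];
        }
      }
      ad_shear.update(j, accept ? 1.0 : 0.0, adapting);
    }

    // --- detectability ridge moves ------------------------------------------
    // The counts pin the product lambda * p, so p_j and the intercept are
    // nearly perfectly anticorrelated.  Propose logit p_j and shift the
    // intercept by log(p_old / p_new), keeping every expected observed
    // count lambda * p fixed; the likelihood changes only through the
    // inter-observer correlation structure, so the move travels the ridge.
    if (dual) {
      for (int j = 0; j < J; ++j) {
        double s = ad_pridge.scale(j);
        double old_lgp = ch.logit_p[j], old_p = ch.p[j];
        double old_b0 = ch.beta(j, 0);
        for (int i = 0; i < n; ++i) { oll[i] = ch.ll(i, j); oXb[i] = ch.Xb(i, j); }
        double lp0 = ch.col_ll(j) + ch.lp_p_one(j) + ch.lp_beta_one(j, 0);
        ch.logit_p[j] = old_lgp + s * norm_rand();
        ch.p[j] = 1.0 / (1.0 + std::exp(-ch.logit_p[j]));
        double shift = std::log(old_p) - std::log(ch.p[j]);
        ch.beta(j, 0) = old_b0 + shift;
        for (int i = 0; i < n; ++i) ch.Xb(i, j) += shift;
        ch.refresh_ll_col(j);
        double lp1 = ch.col_ll(j) + ch.lp_p_one(j) + ch.lp_beta_one(j, 0);
        double d = lp1 - lp0;
        bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
        prop_count[8] += 1;
        if (accept) {
          acc_count[8] += 1;
        } else {
          ch.logit_p[j] = old_lgp; ch.p[j] = old_p; ch.beta(j, 0) = old_b0;
          for (int i = 0; i < n; ++i) { ch.ll(i, j) = oll[i]; ch.Xb(i, j) = oXb[i]; }
        }
        ad_pridge.update(j, accept ? 1.0 : 0.0, adapting);
      }
    }

    // --- per-category covariance-adaptive joint blocks ----------------------
    for (int j = 0; j < J; ++j) {
      int c0 = 0;
      for (int c = 0; c < P; ++c) theta[c0++] = ch.beta(j, c);
      theta[c0++] = ch.log_tau[j];
      if (dual) theta[c0++] = ch.logit_p[j];
      theta_old = theta;

      double s = ad_blk.scale(j);
      bool have_cov = bs[j].chol(Lc);
      for (int a = 0; a < D; ++a) zprop[a] = norm_rand();
      if (have_cov) {
        for (int a = D - 1; a >= 0; --a) {
          double t = 0.0;
          for (int q = 0; q <= a; ++q) t += Lc[a * D + q] * zprop[q];
          theta[a] = theta_old[a] + s * t;
        }
      } else {
        for (int a = 0; a < D; ++a) theta[a] = theta_old[a] + 0.05 * s * zprop[a];
      }

      double lp0 = ch.lp_beta_row(j) + ch.lp_tau_one(j) +
                   (dual ? ch.lp_p_one(j) : 0.0);
      if (ch.centered) lp0 += ch.lp_eps_centered();
      lp0 += ch.col_ll(j);
      double old_lt = ch.log_tau[j], old_t = ch.tau[j];
      double old_lgp = ch.logit_p[j], old_p = ch.p[j];
      for (int i = 0; i < n; ++i) {
        oll[i] = ch.ll(i, j); oXb[i] = ch.Xb(i, j); oeps[i] = ch.eps(i, j);
      }
      c0 = 0;
      for (int c = 0; c < P; ++c) ch.beta(j, c) = theta[c0++];
      ch.log_tau[j] = theta[c0++];
      ch.tau[j] = std::exp(ch.log_tau[j]);
      if (dual) {
        ch.logit_p[j] = theta[c0++];
        ch.p[j] = 1.0 / (1.0 + std::exp(-ch.logit_p[j]));
      }
      ch.refresh_Xb_col(j);
      if (!ch.centered) ch.refresh_eps_col(j);
      ch.refresh_ll_col(j);
      double lp1 = ch.lp_beta_row(j) + ch.lp_tau_one(j) +
                   (dual ? ch.lp_p_one(j) : 0.0);
      if (ch.centered) lp1 += ch.lp_eps_centered();
      lp1 += ch.col_ll(j);
      double d = lp1 - lp0;
      bool accept = R_FINITE(d) && (d >= 0.0 || std::log(unif_rand()) < d);
      prop_count[5] += 1;
      if (accept) {
        acc_count[5] += 1;
      } else {
        c0 = 0;
        for (int c = 0; c < P; ++c) ch.beta(j, c) = theta_old[c0++];
        ch.log_tau[j] = old_lt; ch.tau[j] = old_t;
        if (dual) { ch.logit_p[j] = old_lgp; ch.p[j] = old_p; }
        for (int i = 0; i < n; ++i) {
          ch.ll(i, j) = oll[i]; ch.Xb(i, j) = oXb[i]; ch.eps(i, j) = oeps[i];
        }
      }
      ad_blk.update(j, accept ? 1.0 : 0.0, adapting);

      if (adapting) {
        int cc = 0;
        for (int c = 0; c < P; ++c) theta[cc++] = ch.beta(j, c);
        theta[cc++] = ch.log_tau[j];
        if (dual) theta[cc++] = ch.logit_p[j];
        bs[j].push(theta);
      }
    }

    // --- record -------------------------------------------------------------
    if (iter >= n_warmup && (iter - n_warmup) % thin == thin - 1 &&
        keep < n_keep) {
      int col = 0;
      for (int j = 0; j < J; ++j)
        for (int c = 0; c < P; ++c) draws(keep, col++) = ch.beta(j, c);
      for (int j = 0; j < J; ++j) draws(keep, col++) = ch.tau[j];
      for (int k = 1; k < J; ++k)
        for (int m = 0; m < k; ++m) {
          double om = 0.0;
          for (int q = 0; q <= m; ++q) om += ch.L(k, q) * ch.L(m, q);
          draws(keep, col++) = om;
        }
      if (dual) for (int j = 0; j < J; ++j) draws(keep, col++) = ch.p[j];
      if (save_eps)
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < J; ++j) draws(keep, col++) = ch.eps(i, j);
      draws(keep, col++) = ch.total_lp();
      keep += 1;
    }
  }

  NumericVector acc(9);
  for (int k = 0; k < 9; ++k)
    acc[k] = prop_count[k] > 0 ? acc_count[k] / prop_count[k] : NA_REAL;
  acc.names() = CharacterVector::create("eps", "beta", "p", "tau", "corr",
                                        "block", "shear", "interweave",
                                        "p_ridge");
  return List::create(_["draws"] = draws, _["accept"] = acc);
}

// ---------------------------------------------------------------------------
// Marginal site likelihood for LOO: p(y_i | beta, Sigma, p) with the
// observation-level effect integrated out by Monte Carlo over MVN(0, Sigma).
// ---------------------------------------------------------------------------

// First and second derivatives of the dual-count log-pmf with respect to
// u = log(lambda), used by the Laplace step below.  With l1 = lam p(1-p),
// l2 = lam p^2 and t_k the k-th term of the compound sum,
// dt_k/dlam = -p(2-p) + (y1+y2-k)/lam, so with softmax weights w_k over the
// terms and m_k = y1+y2-k:  dlogf/du = lam dlogf/dlam = -lam p(2-p) + E[m],
// d2logf/du2 = Var[m] - ... (chain rule through u = log lam).
static void dual_logpmf_grad_u(int y1, int y2, double lam, double p,
                               double& g, double& h) {
  if (p >= 1.0) {  // degenerate: Poisson in the common count
    g = (double)y1 - lam;
    h = -lam;
    return;
  }
  const double l1 = lam * p * (1.0 - p);
  const double l2 = lam * p * p;
  const double logl1 = std::log(l1), logl2 = std::log(l2);
  const double base = -(l2 + 2.0 * l1);
  const int mmin = y1 < y2 ? y1 : y2;
  double mx = R_NegInf;
  std::vector<double> terms(mmin + 1);
  for (int k = 0; k <= mmin; ++k) {
    double t = base + k * logl2 - lgfact(k)
             + (y1 - k) * logl1 - lgfact(y1 - k)
             + (y2 - k) * logl1 - lgfact(y2 - k);
    terms[k] = t;
    if (t > mx) mx = t;
  }
  double sw = 0.0, e1 = 0.0, e2 = 0.0;
  for (int k = 0; k <= mmin; ++k) {
    double w = std::exp(terms[k] - mx);
    double m = (double)(y1 + y2 - k);
    sw += w; e1 += w * m; e2 += w * m * m;
  }
  e1 /= sw; e2 /= sw;
  const double c = p * (2.0 - p);      // lam * c = l2 + 2 l1
  // f(lam): dlogf/dlam = -c + e1/lam ; d2logf/dlam2 = (e2-e1^2)/lam^2 - e1/lam^2
  // u = log lam: g = lam f', h = lam^2 f'' + lam f'
  g = -c * lam + e1;
  h = (e2 - e1 * e1) - e1 + (-c * lam + e1);
  // clamp to keep the Newton direction well defined
  if (h > -1e-8) h = -1e-8;
}

// Integrated site likelihood p(y_i | beta_s, Sigma_s, p_s) with the
// observation-level effect integrated out by importance sampling.  The
// integrand p(y_i | e) N(e; 0, Sigma_s) is sharply peaked when counts are
// informative, so for every (site, draw) pair a Laplace approximation is
// built by Newton iteration (the likelihood is separable across categories,
// so the Hessian is Sigma^-1 plus a diagonal), and draws come from a
// defensive half-and-half mixture of the moment-matched normal
// N(mode, 1.7 H^-1) and the prior N(0, Sigma_s), reweighted by the exact
// mixture importance weight so the weights stay bounded in both regimes.
// [[Rcpp::export]]
NumericMatrix site_marginal_loglik_cpp(IntegerMatrix Y1, IntegerMatrix Y2,
                                       NumericMatrix X, NumericVector A,
                                       int likelihood,
                                       NumericMatrix beta_draws,  // S x J*P
                                       NumericMatrix Lsig_draws,  // S x J*J
                                       NumericMatrix p_draws,     // S x J
                                       int n_eps) {
  const int n = Y1.nrow(), J = Y1.ncol(), P = X.ncol();
  const int S = beta_draws.nrow();
  const double infl2 = 1.7;            // proposal covariance inflation
  NumericMatrix out(n, S);
  RNGScope scope;
  std::vector<double> xb(J), e(J), z(J), v(J), g(J), h(J), mode(J),
      grad(J), del(J), lm(n_eps);
  std::vector<double> Ls(J * J), Sinv(J * J), M(J * J), Lm(J * J);
  const double log_half = std::log(0.5);

  for (int s = 0; s < S; ++s) {
    for (int a = 0; a < J * J; ++a) Ls[a] = Lsig_draws(s, a);
    double half_logdet_s = 0.0;
    for (int j = 0; j < J; ++j) half_logdet_s += std::log(Ls[j * J + j]);
    // Sigma^-1 = L^-T L^-1
    {
      std::vector<double> Li(J * J, 0.0);
      for (int c = 0; c < J; ++c) {
        Li[c * J + c] = 1.0 / Ls[c * J + c];
        for (int r = c + 1; r < J; ++r) {
          double t = 0.0;
          for (int q = c; q < r; ++q) t += Ls[r * J + q] * Li[q * J + c];
          Li[r * J + c] = -t / Ls[r * J + r];
        }
      }
      for (int a = 0; a < J; ++a)
        for (int b = 0; b <= a; ++b) {
          double t = 0.0;
          for (int q = a; q < J; ++q) t += Li[q * J + a] * Li[q * J + b];
          Sinv[a * J + b] = Sinv[b * J + a] = t;
        }
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < J; ++j) {
        double t = 0.0;
        for (int c = 0; c < P; ++c) t += X(i, c) * beta_draws(s, j * P + c);
        xb[j] = t;
      }
      // --- Newton iterations for the mode of p(y|e) N(e; 0, Sigma) ---------
      for (int j = 0; j < J; ++j) mode[j] = 0.0;
      for (int it = 0; it < 25; ++it) {
        for (int j = 0; j < J; ++j) {
          double lam = A[i] * std::exp(xb[j] + mode[j]);
          if (likelihood == 0) {
            dual_logpmf_grad_u(Y1(i, j), Y2(i, j), lam, p_draws(s, j),
                               g[j], h[j]);
          } else {
            g[j] = (double)Y1(i, j) - lam;
            h[j] = -lam;
            if (h[j] > -1e-8) h[j] = -1e-8;
          }
        }
        // grad = g - Sinv mode ; M = Sinv + diag(-h)
        for (int a = 0; a < J; ++a) {
          double t = g[a];
          for (int b = 0; b < J; ++b) t -= Sinv[a * J + b] * mode[b];
          grad[a] = t;
        }
        for (int a = 0; a < J * J; ++a) M[a] = Sinv[a];
        for (int a = 0; a < J; ++a) M[a * J + a] += -h[a];
        // chol M -> Lm, solve M del = grad
        bool ok = true;
        for (int a = 0; a < J && ok; ++a) {
          for (int b = 0; b <= a; ++b) {
            double t = M[a * J + b];
            for (int q = 0; q < b; ++q) t -= Lm[a * J + q] * Lm[b * J + q];
            if (a == b) {
              if (t <= 0.0) { ok = false; break; }
              Lm[a * J + a] = std::sqrt(t);
            } else {
              Lm[a * J + b] = t / Lm[b * J + b];
            }
          }
        }
        if (!ok) break;
        for (int a = 0; a < J; ++a) {
          double t = grad[a];
          for (int q = 0; q < a; ++q) t -= Lm[a * J + q] * v[q];
          v[a] = t / Lm[a * J + a];
        }
        for (int a = J - 1; a >= 0; --a) {
          double t = v[a];
          for (int q = a + 1; q < J; ++q) t -= Lm[q * J + a] * del[q];
          del[a] = t / Lm[a * J + a];
        }
        double step2 = 0.0;
        for (int a = 0; a < J; ++a) {
          if (del[a] > 2.0) del[a] = 2.0;       // damp huge first steps
          if (del[a] < -2.0) del[a] = -2.0;
          mode[a] += del[a];
          step2 += del[a] * del[a];
        }
        if (step2 < 1e-10) break;
      }
      // final curvature at the mode (Lm, M left from the last iteration)
      double half_logdet_m = 0.0;
      for (int j = 0; j < J; ++j) half_logdet_m += std::log(Lm[j * J + j]);
      // proposal component: N(mode, infl2 * M^-1)
      // sampling: solve Lm^T w = z  =>  w ~ N(0, M^-1)
      const double half_log_infl = 0.5 * (double)J * std::log(infl2);

      double mx = R_NegInf;
      for (int m = 0; m < n_eps; ++m) {
        bool from_match = (m % 2 == 1);
        for (int j = 0; j < J; ++j) z[j] = norm_rand();
        if (from_match) {
          for (int a = J - 1; a >= 0; --a) {
            double t = z[a];
            for (int q = a + 1; q < J; ++q) t -= Lm[q * J + a] * v[q];
            v[a] = t / Lm[a * J + a];
          }
          for (int j = 0; j < J; ++j)
            e[j] = mode[j] + std::sqrt(infl2) * v[j];
        } else {
          for (int j = 0; j < J; ++j) {
            double t = 0.0;
            for (int q = 0; q <= j; ++q) t += Ls[j * J + q] * z[q];
            e[j] = t;
          }
        }
        // log N(e; 0, Sigma) up to the shared 2 pi constant
        double qs = 0.0;
        for (int j = 0; j < J; ++j) {
          double t = e[j];
          for (int q = 0; q < j; ++q) t -= Ls[j * J + q] * v[q];
          v[j] = t / Ls[j * J + j];
          qs += v[j] * v[j];
        }
        double log_target = -0.5 * qs - half_logdet_s;
        // log N(e; mode, infl2 M^-1): quadratic form (e-mode)' M (e-mode)
        double qm = 0.0;
        for (int j = 0; j < J; ++j) {
          double t = 0.0;
          for (int q = 0; q < J; ++q)
            t += M[j * J + q] * (e[q] - mode[q]);
          qm += (e[j] - mode[j]) * t;
        }
        double log_match = -0.5 * qm / infl2 + half_logdet_m - half_log_infl;
        double big = log_target > log_match ? log_target : log_match;
        double log_q = big + std::log(std::exp(log_target - big) +
                                      std::exp(log_match - big)) + log_half;
        double llm = log_target - log_q;
        for (int j = 0; j < J; ++j) {
          double lam = A[i] * std::exp(xb[j] + e[j]);
          if (likelihood == 0)
            llm += dual_logpmf_one(Y1(i, j), Y2(i, j), lam, p_draws(s, j));
          else
            llm += R::dpois(Y1(i, j), lam, 1);
        }
        lm[m] = llm;
        if (llm > mx) mx = llm;
      }
      double acc = 0.0;
      for (int m = 0; m < n_eps; ++m) acc += std::exp(lm[m] - mx);
      out(i, s) = R_FINITE(mx) ? mx + std::log(acc / n_eps) : R_NegInf;
    }
  }
  return out;
}
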