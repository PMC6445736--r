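// MCMC samplers for the location-scale mixed model (random intercept +/-
// slope with subject-specific log-normal residual SD) and the shared-
// random-effects joint model with piecewise-constant baseline hazard.
//
// Scheme: Metropolis-within-Gibbs.  Conjugate draws where the full
// conditional is normal (fixed effects; random effects given the residual
// SD in the longitudinal-only model; mu_sigma), adaptive random-walk
// Metropolis elsewhere (log residual SDs, variance-component SDs and
// correlations, log baseline-hazard levels, association coefficients).
// In the joint model the random effects b_i are proposed from their
// longitudinal full conditional and accepted with the survival-likelihood
// ratio (independence Metropolis-Hastings).  Random-walk step sizes are
// tuned by Robbins-Monro during burn-in (target acceptance 0.44) and
// frozen afterwards.  All randomness comes from R's RNG, so set.seed()
// on the R side makes runs reproducible.
//
// The random-intercept case (q = 1) is the workhorse of the simulation
// harness, so its subject loop is written in plain scalar arithmetic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ETA_MAX = 50.0;  // bound on hazard linear predictors

// Population covariance of (b0[, b1], log sigma): SDs tau, correlations
// r01 (intercept-slope), r0s, r1s (random effects vs log SD).
struct PopCov {
  int d, q;
  arma::vec tau;
  double r01, r0s, r1s;
  arma::mat Sigma, Omega;
  double logdet;
  bool build() {
    arma::mat R(d, d, arma::fill::eye);
    if (q == 1) {
      R(0, 1) = R(1, 0) = r0s;
    } else {
      R(0, 1) = R(1, 0) = r01;
      R(0, 2) = R(2, 0) = r0s;
      R(1, 2) = R(2, 1) = r1s;
    }
    Sigma = arma::diagmat(tau) * R * arma::diagmat(tau);
    arma::mat L;
    if (!arma::chol(L, Sigma, "lower")) return false;
    double ld = 0.0;
    for (int j = 0; j < d; ++j) ld += std::log(L(j, j));
    logdet = 2.0 * ld;
    return arma::inv_sympd(Omega, Sigma);
  }
};

struct Adapt {
  arma::vec ls;
  double target;
  void init(int n, double s0, double tgt) {
    ls.set_size(n); ls.fill(std::log(s0)); target = tgt;
  }
  double step(int i) const { return std::exp(ls[i]); }
  void tune(int i, bool accepted, int iter) {
    double g = std::min(0.3, 2.0 / std::sqrt((double)iter + 1.0));
    ls[i] += g * ((accepted ? 1.0 : 0.0) - target);
    ls[i] = std::min(5.0, std::max(-10.0, ls[i]));
  }
};

// Conditional moments of b | s and s | b under the population MVN.
struct CondMoments {
  arma::mat Vbinv;  // inverse cov of b | s (q x q)
  arma::vec cb;     // E[b | s] = cb * (s - mu_sigma)
  arma::vec cs;     // E[s | b] = mu_sigma + dot(cs, b)
  double vs;        // var of s | b
  void compute(const PopCov& pc) {
    int q = pc.q, d = pc.d;
    arma::mat Sbb = pc.Sigma.submat(0, 0, q - 1, q - 1);
    arma::vec Sbs = pc.Sigma.submat(0, d - 1, q - 1, d - 1);
    double Sss = pc.Sigma(d - 1, d - 1);
    cb = Sbs / Sss;
    Vbinv = arma::inv_sympd(Sbb - Sbs * Sbs.t() / Sss);
    arma::vec tmp = arma::solve(Sbb, Sbs);
    cs = tmp;
    vs = Sss - arma::dot(Sbs, tmp);
  }
};

static arma::vec draw_mvn_from_precision(const arma::mat& P, const arma::vec& h) {
  arma::mat L = arma::chol(P, "lower");
  arma::vec mu = arma::solve(arma::trimatu(L.t()),
                             arma::solve(arma::trimatl(L), h));
  arma::vec z(P.n_rows);
  for (arma::uword k = 0; k < P.n_rows; ++k) z[k] = R::rnorm(0.0, 1.0);
  return mu + arma::solve(arma::trimatu(L.t()), z);
}

// Conjugate update of fixed effects beta given random effects and sigma_i.
static void update_beta(arma::vec& beta, const arma::vec& y,
                        const arma::mat& X, const arma::mat& u,
                        const arma::ivec& s0, const arma::ivec& slen,
                        bool has_slope, const arma::vec& tt,
                        double prior_sd) {
  const int p = X.n_cols, N = s0.n_elem;
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  std::vector<const double*> xc(p);
  for (int k = 0; k < p; ++k) xc[k] = X.colptr(k);
  const double* yp = y.memptr();
  const double* tp = tt.memptr();
  for (int i = 0; i < N; ++i) {
    double w = std::exp(-2.0 * u(i, u.n_cols - 1));
    double b0 = u(i, 0), b1 = has_slope ? u(i, 1) : 0.0;
    for (int j = s0[i]; j < s0[i] + slen[i]; ++j) {
      double yt = yp[j] - b0 - (has_slope ? b1 * tp[j] : 0.0);
      for (int k = 0; k < p; ++k) {
        double xk = xc[k][j];
        b[k] += w * yt * xk;
        for (int l = 0; l <= k; ++l) A(k, l) += w * xk * xc[l][j];
      }
    }
  }
  A = arma::symmatl(A);
  A.diag() += 1.0 / (prior_sd * prior_sd);
  beta = draw_mvn_from_precision(A, b);
}

// Conjugate update of mu_sigma (the only free component of the MVN mean).
static void update_mu_sigma(double& mu_sigma, const arma::mat& u,
                            const PopCov& pc, double prior_sd) {
  int N = u.n_rows, d = pc.d;
  arma::rowvec cs = arma::sum(u, 0);
  double prec = N * pc.Omega(d - 1, d - 1) + 1.0 / (prior_sd * prior_sd);
  double lin = arma::dot(pc.Omega.row(d - 1), cs);
  mu_sigma = R::rnorm(lin / prec, std::sqrt(1.0 / prec));
}

// Random-walk updates of the free SD / correlation parameters given the
// scatter matrix S of (u_i - e*mu_sigma).  Uniform priors: SDs on
// (0, sd_upper), correlations on (-1, 1); proposals outside the support
// or giving a non-positive-definite covariance are rejected.
static void update_cov_params(PopCov& pc, const arma::mat& S, int N,
                              bool correlated, double sd_upper,
                              Adapt& ad, int iter, bool adapting) {
  int nfree = pc.d + (pc.q == 2 ? 1 : 0) + (correlated ? pc.q : 0);
  double cur = -0.5 * N * pc.logdet - 0.5 * arma::trace(pc.Omega * S);
  for (int j = 0; j < nfree; ++j) {
    PopCov trial = pc;
    double* slot;
    bool is_sd = false;
    if (j < pc.d) { slot = &trial.tau[j]; is_sd = true; }
    else if (pc.q == 2 && j == pc.d) slot = &trial.r01;
    else {
      int jc = j - pc.d - (pc.q == 2 ? 1 : 0);
      slot = (jc == 0) ? &trial.r0s : &trial.r1s;
    }
    double prop = *slot + ad.step(j) * R::rnorm(0.0, 1.0);
    bool ok = is_sd ? (prop > 0.0 && prop < sd_upper)
                    : (prop > -1.0 && prop < 1.0);
    bool accepted = false;
    if (ok) {
      *slot = prop;
      if (trial.build()) {
        double newll = -0.5 * N * trial.logdet
                       - 0.5 * arma::trace(trial.Omega * S);
        if (std::log(R::runif(0.0, 1.0)) < newll - cur) {
          pc = trial; cur = newll; accepted = true;
        }
      }
    }
    if (adapting) ad.tune(j, accepted, iter);
  }
}

// Longitudinal sufficient statistics of one subject given residuals
// r = y - X beta.
struct SubjStats {
  double z11, z12, z22, zr1, zr2;
  int n;
  void compute(const double* rp, const double* tp, int a, int n_i,
               bool has_slope) {
    n = n_i; z11 = n_i; z12 = z22 = zr1 = zr2 = 0.0;
    for (int j = a; j < a + n_i; ++j) {
      zr1 += rp[j];
      if (has_slope) {
        z12 += tp[j]; z22 += tp[j] * tp[j]; zr2 += tp[j] * rp[j];
      }
    }
  }
};

// Draw b_i from its longitudinal-conditional posterior given s_i
// (general-q path).
static arma::vec draw_b_conditional(const SubjStats& st, const CondMoments& cm,
                                    double s, double mu_sigma, int q) {
  double inv_s2 = std::exp(-2.0 * s);
  arma::vec mb = cm.cb * (s - mu_sigma);
  arma::vec h = cm.Vbinv * mb;
  if (q == 1) {
    double prec = cm.Vbinv(0, 0) + st.z11 * inv_s2;
    double mean = (h[0] + st.zr1 * inv_s2) / prec;
    arma::vec out(1);
    out[0] = R::rnorm(mean, std::sqrt(1.0 / prec));
    return out;
  }
  arma::mat P = cm.Vbinv;
  P(0, 0) += st.z11 * inv_s2; P(0, 1) += st.z12 * inv_s2;
  P(1, 0) += st.z12 * inv_s2; P(1, 1) += st.z22 * inv_s2;
  arma::vec hv = h;
  hv[0] += st.zr1 * inv_s2; hv[1] += st.zr2 * inv_s2;
  return draw_mvn_from_precision(P, hv);
}

static inline double ssr_q1(const double* rp, int a, int n_i, double b0) {
  double ssr = 0.0;
  for (int j = a; j < a + n_i; ++j) {
    double e = rp[j] - b0;
    ssr += e * e;
  }
  return ssr;
}

static double subj_ssr(const double* rp, const double* tp, int a, int n_i,
                       const arma::mat& u, int i, bool has_slope) {
  double ssr = 0.0;
  for (int j = a; j < a + n_i; ++j) {
    double e = rp[j] - u(i, 0) - (has_slope ? u(i, 1) * tp[j] : 0.0);
    ssr += e * e;
  }
  return ssr;
}

// ---------------------------------------------------------------------------
// Location-scale mixed model (longitudinal only)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List locscale_mcmc_cpp(const arma::vec& y, const arma::ivec& subj_start,
                       const arma::ivec& subj_len, const arma::vec& tt,
                       const arma::mat& X, bool has_slope, bool correlated,
                       int burn, int n_keep, int thin,
                       double sd_upper, double loc_prior_sd,
                       arma::vec beta, arma::mat u, double mu_sigma,
                       arma::vec tau, double r01, double r0s, double r1s,
                       bool fix_beta, bool fix_pop, bool store_subject) {
  const int N = subj_start.n_elem;
  const int p = X.n_cols;
  const int q = has_slope ? 2 : 1;
  const int d = q + 1;
  const int n_iter = burn + n_keep * thin;

  PopCov pc; pc.d = d; pc.q = q; pc.tau = tau;
  pc.r01 = r01; pc.r0s = r0s; pc.r1s = r1s;
  if (!pc.build()) stop("initial covariance not positive definite");

  Adapt ad_s;   ad_s.init(N, 0.5, 0.44);
  Adapt ad_cov; ad_cov.init(d + 4, 0.1, 0.44);

  const int n_pop = p + 1 + d + 3;
  arma::mat pop_out(n_keep, n_pop);
  arma::mat sub_b0, sub_b1, sub_sig;
  if (store_subject) {
    sub_b0.set_size(n_keep, N); sub_sig.set_size(n_keep, N);
    if (has_slope) sub_b1.set_size(n_keep, N);
  }
  arma::vec mean_b0(N, arma::fill::zeros), mean_b1(N, arma::fill::zeros),
            mean_sig(N, arma::fill::zeros);
  double acc_sig = 0.0; long n_acc_try = 0;

  CondMoments cm; cm.compute(pc);
  arma::vec r = y - X * beta;
  SubjStats st;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burn;
    if (!fix_beta) {
      update_beta(beta, y, X, u, subj_start, subj_len, has_slope, tt,
                  loc_prior_sd);
      r = y - X * beta;
    }
    const double* rp = r.memptr();
    const double* tp = tt.memptr();
    // fast scalar conditionals for the random-intercept model
    const double cb0 = cm.cb[0], cs0 = cm.cs[0];
    const double Vbinv00 = cm.Vbinv(0, 0), vs = cm.vs;
    for (int i = 0; i < N; ++i) {
      int a = subj_start[i], n_i = subj_len[i];
      double s = u(i, d - 1);
      if (q == 1) {
        double inv_s2 = std::exp(-2.0 * s);
        double zr1 = 0.0;
        for (int j = a; j < a + n_i; ++j) zr1 += rp[j];
        double prec = Vbinv00 + n_i * inv_s2;
        double mean = (Vbinv00 * cb0 * (s - mu_sigma) + zr1 * inv_s2) / prec;
        u(i, 0) = R::rnorm(mean, std::sqrt(1.0 / prec));
      } else {
        st.compute(rp, tp, a, n_i, has_slope);
        arma::vec bnew = draw_b_conditional(st, cm, s, mu_sigma, q);
        for (int k = 0; k < q; ++k) u(i, k) = bnew[k];
      }
      double SSR = (q == 1) ? ssr_q1(rp, a, n_i, u(i, 0))
                            : subj_ssr(rp, tp, a, n_i, u, i, has_slope);
      double ms = (q == 1) ? mu_sigma + cs0 * u(i, 0)
                           : mu_sigma + arma::dot(cm.cs, u.row(i).head(q).t());
      double s_new = s + ad_s.step(i) * R::rnorm(0.0, 1.0);
      double ll_cur = -n_i * s - 0.5 * SSR * std::exp(-2.0 * s)
                      - 0.5 * (s - ms) * (s - ms) / vs;
      double ll_new = -n_i * s_new - 0.5 * SSR * std::exp(-2.0 * s_new)
                      - 0.5 * (s_new - ms) * (s_new - ms) / vs;
      bool acc = std::log(R::runif(0.0, 1.0)) < ll_new - ll_cur;
      if (acc) u(i, d - 1) = s_new;
      if (adapting) ad_s.tune(i, acc, it);
      else { acc_sig += acc; n_acc_try++; }
    }
    if (!fix_pop) {
      update_mu_sigma(mu_sigma, u, pc, loc_prior_sd);
      arma::mat uc = u;
      uc.col(d - 1) -= mu_sigma;
      arma::mat S = uc.t() * uc;
      update_cov_params(pc, S, N, correlated, sd_upper, ad_cov, it, adapting);
      cm.compute(pc);
    }
    if (it >= burn && (it - burn) % thin == thin - 1 && kept < n_keep) {
      int c = 0;
      for (int k = 0; k < p; ++k) pop_out(kept, c++) = beta[k];
      pop_out(kept, c++) = mu_sigma;
      for (int k = 0; k < d; ++k) pop_out(kept, c++) = pc.tau[k];
      pop_out(kept, c++) = pc.r01;
      pop_out(kept, c++) = pc.r0s;
      pop_out(kept, c++) = pc.r1s;
      for (int i = 0; i < N; ++i) {
        double sig = std::exp(u(i, d - 1));
        mean_b0[i] += u(i, 0); mean_sig[i] += sig;
        if (has_slope) mean_b1[i] += u(i, 1);
        if (store_subject) {
          sub_b0(kept, i) = u(i, 0); sub_sig(kept, i) = sig;
          if (has_slope) sub_b1(kept, i) = u(i, 1);
        }
      }
      kept++;
    }
  }
  mean_b0 /= kept; mean_sig /= kept;
  if (has_slope) mean_b1 /= kept;

  List subj_draws = R_NilValue;
  if (store_subject)
    subj_draws = List::create(_["b0"] = sub_b0, _["sigma"] = sub_sig,
                              _["b1"] = has_slope ? wrap(sub_b1) : R_NilValue);
  return List::create(_["pop"] = pop_out,
                      _["mean_b0"] = mean_b0, _["mean_b1"] = mean_b1,
                      _["mean_sigma"] = mean_sig,
                      _["subject_draws"] = subj_draws,
                      _["accept_sigma"] = n_acc_try ? acc_sig / n_acc_try : NA_REAL);
}

// ---------------------------------------------------------------------------
// Joint model: location-scale longitudinal submodel + piecewise-constant
// baseline hazard with shared random effects (b0[, b1], sigma).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List joint_mcmc_cpp(const arma::vec& y, const arma::ivec& subj_start,
                    const arma::ivec& subj_len, const arma::vec& tt,
                    const arma::mat& X, bool has_slope, bool correlated,
                    const arma::ivec& delta, const arma::ivec& kidx,
                    const arma::mat& Occ, const arma::mat& W,
                    int burn, int n_keep, int thin,
                    double sd_upper, double loc_prior_sd,
                    arma::vec beta, arma::mat u, double mu_sigma,
                    arma::vec tau, double r01, double r0s, double r1s,
                    arma::vec alpha, arma::vec gamma, arma::vec logh,
                    bool fix_alpha, bool store_subject) {
  const int N = subj_start.n_elem;
  const int p = X.n_cols;
  const int q = has_slope ? 2 : 1;
  const int d = q + 1;
  const int K = Occ.n_cols;
  const int w = W.n_cols;
  const int n_iter = burn + n_keep * thin;

  PopCov pc; pc.d = d; pc.q = q; pc.tau = tau;
  pc.r01 = r01; pc.r0s = r0s; pc.r1s = r1s;
  if (!pc.build()) stop("initial covariance not positive definite");

  arma::vec dk(K, arma::fill::zeros);  // events per hazard interval (fixed)
  for (int i = 0; i < N; ++i) if (delta[i] == 1) dk[kidx[i]] += 1.0;

  Adapt ad_s;   ad_s.init(N, 0.5, 0.44);
  Adapt ad_cov; ad_cov.init(d + 4, 0.1, 0.44);
  Adapt ad_h;   ad_h.init(K, 0.3, 0.44);
  Adapt ad_a;   ad_a.init(q + 1 + w, 0.02, 0.44);

  const int n_pop = p + 1 + d + 3 + (q + 1) + w + K;
  arma::mat pop_out(n_keep, n_pop);
  arma::mat sub_b0, sub_b1, sub_sig;
  if (store_subject) {
    sub_b0.set_size(n_keep, N); sub_sig.set_size(n_keep, N);
    if (has_slope) sub_b1.set_size(n_keep, N);
  }
  arma::vec mean_b0(N, arma::fill::zeros), mean_b1(N, arma::fill::zeros),
            mean_sig(N, arma::fill::zeros);

  CondMoments cm; cm.compute(pc);
  arma::vec r = y - X * beta;
  arma::vec h0 = arma::exp(logh);
  arma::vec eta(N);
  auto eta_of = [&](int i) {
    double e = 0.0;
    for (int k = 0; k < q; ++k) e += alpha[k] * u(i, k);
    e += alpha[q] * std::exp(u(i, q));
    for (int k = 0; k < w; ++k) e += gamma[k] * W(i, k);
    return e;
  };
  SubjStats st;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burn;
    update_beta(beta, y, X, u, subj_start, subj_len, has_slope, tt,
                loc_prior_sd);
    r = y - X * beta;
    const double* rp = r.memptr();
    const double* tp = tt.memptr();

    arma::vec H0base = Occ * h0;      // baseline cumulative hazard at T_i
    for (int i = 0; i < N; ++i) eta[i] = eta_of(i);

    const double cb0 = cm.cb[0], cs0 = cm.cs[0];
    const double Vbinv00 = cm.Vbinv(0, 0), vs = cm.vs;
    for (int i = 0; i < N; ++i) {
      int a = subj_start[i], n_i = subj_len[i];
      double s = u(i, d - 1);

      // b_i: independence MH from the longitudinal conditional, accepted
      // with the survival-likelihood ratio
      double eta_new = eta[i];
      double b_old0 = u(i, 0), b_old1 = has_slope ? u(i, 1) : 0.0;
      if (q == 1) {
        double inv_s2 = std::exp(-2.0 * s);
        double zr1 = 0.0;
        for (int j = a; j < a + n_i; ++j) zr1 += rp[j];
        double prec = Vbinv00 + n_i * inv_s2;
        double mean = (Vbinv00 * cb0 * (s - mu_sigma) + zr1 * inv_s2) / prec;
        double bnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        eta_new += alpha[0] * (bnew - b_old0);
        u(i, 0) = bnew;
      } else {
        st.compute(rp, tp, a, n_i, has_slope);
        arma::vec bnew = draw_b_conditional(st, cm, s, mu_sigma, q);
        for (int k = 0; k < q; ++k) {
          eta_new += alpha[k] * (bnew[k] - u(i, k));
          u(i, k) = bnew[k];
        }
      }
      if (std::abs(eta_new) < ETA_MAX) {
        double la = delta[i] * (eta_new - eta[i])
                    - H0base[i] * (std::exp(eta_new) - std::exp(eta[i]));
        if (std::log(R::runif(0.0, 1.0)) < la) {
          eta[i] = eta_new;
        } else {                      // revert
          u(i, 0) = b_old0;
          if (has_slope) u(i, 1) = b_old1;
        }
      } else {
        u(i, 0) = b_old0;
        if (has_slope) u(i, 1) = b_old1;
      }

      // s_i: RW with longitudinal + prior + survival terms
      double SSR = (q == 1) ? ssr_q1(rp, a, n_i, u(i, 0))
                            : subj_ssr(rp, tp, a, n_i, u, i, has_slope);
      double ms = (q == 1) ? mu_sigma + cs0 * u(i, 0)
                           : mu_sigma + arma::dot(cm.cs, u.row(i).head(q).t());
      double s_new = s + ad_s.step(i) * R::rnorm(0.0, 1.0);
      bool acc = false;
      if (s_new < 20.0) {
        double eta_s = eta[i] + alpha[q] * (std::exp(s_new) - std::exp(s));
        if (std::abs(eta_s) < ETA_MAX) {
          double ll_cur = -n_i * s - 0.5 * SSR * std::exp(-2.0 * s)
                          - 0.5 * (s - ms) * (s - ms) / vs
                          + delta[i] * eta[i] - H0base[i] * std::exp(eta[i]);
          double ll_new = -n_i * s_new - 0.5 * SSR * std::exp(-2.0 * s_new)
                          - 0.5 * (s_new - ms) * (s_new - ms) / vs
                          + delta[i] * eta_s - H0base[i] * std::exp(eta_s);
          acc = std::log(R::runif(0.0, 1.0)) < ll_new - ll_cur;
          if (acc) { u(i, d - 1) = s_new; eta[i] = eta_s; }
        }
      }
      if (adapting) ad_s.tune(i, acc, it);
    }

    update_mu_sigma(mu_sigma, u, pc, loc_prior_sd);
    {
      arma::mat uc = u;
      uc.col(d - 1) -= mu_sigma;
      arma::mat S = uc.t() * uc;
      update_cov_params(pc, S, N, correlated, sd_upper, ad_cov, it, adapting);
      cm.compute(pc);
    }

    // baseline hazard levels: RW on log h0_k with N(0, loc_prior_sd^2) prior
    arma::vec expeta = arma::exp(eta);
    arma::vec Ek = Occ.t() * expeta;
    for (int k = 0; k < K; ++k) {
      double lh = logh[k];
      double lh_new = lh + ad_h.step(k) * R::rnorm(0.0, 1.0);
      double la = dk[k] * (lh_new - lh)
                  - (std::exp(lh_new) - std::exp(lh)) * Ek[k]
                  - 0.5 * (lh_new * lh_new - lh * lh)
                    / (loc_prior_sd * loc_prior_sd);
      bool acc = std::log(R::runif(0.0, 1.0)) < la;
      if (acc) logh[k] = lh_new;
      if (adapting) ad_h.tune(k, acc, it);
    }
    h0 = arma::exp(logh);
    H0base = Occ * h0;

    // association and baseline-covariate coefficients: componentwise RW
    if (!fix_alpha) {
      arma::mat A(N, q + 1 + w);
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < q; ++k) A(i, k) = u(i, k);
        A(i, q) = std::exp(u(i, q));
        for (int k = 0; k < w; ++k) A(i, q + 1 + k) = W(i, k);
      }
      for (int jpar = 0; jpar < q + 1 + w; ++jpar) {
        double cur = (jpar <= q) ? alpha[jpar] : gamma[jpar - q - 1];
        double prop = cur + ad_a.step(jpar) * R::rnorm(0.0, 1.0);
        double dpar = prop - cur;
        double la = -0.5 * (prop * prop - cur * cur)
                    / (loc_prior_sd * loc_prior_sd);
        const double* ac = A.colptr(jpar);
        bool ok = true;
        for (int i = 0; i < N; ++i) {
          double en = eta[i] + dpar * ac[i];
          if (std::abs(en) >= ETA_MAX) { ok = false; break; }
          la += delta[i] * dpar * ac[i]
                - H0base[i] * (std::exp(en) - std::exp(eta[i]));
        }
        bool acc = ok && std::log(R::runif(0.0, 1.0)) < la;
        if (acc) {
          eta += dpar * A.col(jpar);
          if (jpar <= q) alpha[jpar] = prop; else gamma[jpar - q - 1] = prop;
        }
        if (adapting) ad_a.tune(jpar, acc, it);
      }
    }

    if (it >= burn && (it - burn) % thin == thin - 1 && kept < n_keep) {
      int c = 0;
      for (int k = 0; k < p; ++k) pop_out(kept, c++) = beta[k];
      pop_out(kept, c++) = mu_sigma;
      for (int k = 0; k < d; ++k) pop_out(kept, c++) = pc.tau[k];
      pop_out(kept, c++) = pc.r01;
      pop_out(kept, c++) = pc.r0s;
      pop_out(kept, c++) = pc.r1s;
      for (int k = 0; k < q + 1; ++k) pop_out(kept, c++) = alpha[k];
      for (int k = 0; k < w; ++k) pop_out(kept, c++) = gamma[k];
      for (int k = 0; k < K; ++k) pop_out(kept, c++) = std::exp(logh[k]);
      for (int i = 0; i < N; ++i) {
        double sig = std::exp(u(i, d - 1));
        mean_b0[i] += u(i, 0); mean_sig[i] += sig;
        if (has_slope) mean_b1[i] += u(i, 1);
        if (store_subject) {
          sub_b0(kept, i) = u(i, 0); sub_sig(kept, i) = sig;
          if (has_slope) sub_b1(kept, i) = u(i, 1);
        }
      }
      kept++;
    }
  }
  mean_b0 /= kept; mean_sig /= kept;
  if (has_slope) mean_b1 /= kept;

  List subj_draws = R_NilValue;
  if (store_subject)
    subj_draws = List::create(_["b0"] = sub_b0, _["sigma"] = sub_sig,
                              _["b1"] = has_slope ? wrap(sub_b1) : R_NilValue);
  return List::create(_["pop"] = pop_out,
                      _["mean_b0"] = mean_b0, _["mean_b1"] = mean_b1,
                      _["mean_sigma"] = mean_sig,
                      _["subject_draws"] = subj_draws);
}
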