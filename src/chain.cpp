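// Metropolis-within-Gibbs cores for the variance-ratio animal models.
//
// Both samplers share the same second stage: a multivariate normal
// likelihood (on the data y for the linear model, on the latent log-means
// lambda* for the zero-inflated Poisson model) with covariance
//   V = sigma2_P * [ K_A h2 + K_L l2 + K_C c2 + I (1 - h2 - l2 - c2) ],
// flat priors on beta and sigma2_P, and the joint prior of (h2, l2, c2)
// uniform on the unit simplex.  Updates: beta and sigma2_P by Gibbs, each
// ratio by a reflected Gaussian random-walk Metropolis step.
//
// The per-iteration normalized conditional density of each ratio at zero
// (the Savage-Dickey numerator trace) is computed exactly from a single
// Cholesky of the bracketed matrix K: writing V(t) = K + (t - r) (K_j - I)
// and B = L^-1 (K_j - I) L^-T with K = L L', the log-determinant and
// quadratic form along the whole grid follow from the eigenvalues of B in
// O(n) per grid point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log1pexp_d(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double logsumexp2(double a, double b) {
  if (!std::isfinite(a) && a < 0) return b;
  if (!std::isfinite(b) && b < 0) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Fold a proposal back into [lo, hi] by reflection at both boundaries.
static double reflect_interval(double x, double lo, double hi) {
  double L = hi - lo;
  if (L <= 0.0) return lo;
  double w = (x - lo) / (2.0 * L);
  double z = (w - std::floor(w)) * 2.0 * L;
  if (z > L) z = 2.0 * L - z;
  return lo + z;
}

// One-observation ZIP log-likelihood term, dropping y! (constant in
// lambda*).  lam = exp(lamstar) with overflow guard.
static inline double zip_obs_term(double y, double lamstar, double pstar) {
  double lam = (lamstar < 690.0) ? std::exp(lamstar) : R_PosInf;
  if (y == 0.0) {
    return logsumexp2(pstar, -lam);
  }
  if (!std::isfinite(lam)) return R_NegInf;
  return -lam + lamstar * y;
}

struct SecondStage {
  const arma::mat &Ka, &Kl, &Kc;
  const arma::mat &X;
  int n, p;
  arma::vec beta;
  arma::vec r;      // (h2, l2, c2)
  double s2;
  arma::mat K, Lk;
  double logdetK;
  double S_cur;     // e' K^-1 e for current e and K

  SecondStage(const arma::mat& Ka_, const arma::mat& Kl_, const arma::mat& Kc_,
              const arma::mat& X_, arma::vec beta0, arma::vec r0, double s20)
    : Ka(Ka_), Kl(Kl_), Kc(Kc_), X(X_), n(Ka_.n_rows), p(X_.n_cols),
      beta(beta0), r(r0), s2(s20), S_cur(0.0) {
    rebuildK();
  }

  const arma::mat& kernel(int j) const { return j == 0 ? Ka : (j == 1 ? Kl : Kc); }

  void rebuildK() {
    K = r(0) * Ka + r(1) * Kl + r(2) * Kc;
    K.diag() += 1.0 - arma::accu(r);
    if (!arma::chol(Lk, K, "lower"))
      stop("Cholesky factorization of the covariance kernel failed");
    logdetK = 2.0 * arma::accu(arma::log(Lk.diag()));
  }

  // Gibbs draw of beta given (y, K, s2); flat prior.
  void update_beta(const arma::vec& y) {
    if (p == 0) return;
    arma::mat W = arma::solve(arma::trimatl(Lk), X);
    arma::vec wy = arma::solve(arma::trimatl(Lk), y);
    arma::mat G = W.t() * W;
    arma::vec h = W.t() * wy;
    arma::mat Lg;
    if (!arma::chol(Lg, G, "lower")) stop("X' V^-1 X is singular");
    arma::vec mean = arma::solve(arma::trimatu(Lg.t()),
                                 arma::solve(arma::trimatl(Lg), h));
    arma::vec z(p);
    for (int k = 0; k < p; ++k) z(k) = R::norm_rand();
    beta = mean + std::sqrt(s2) * arma::solve(arma::trimatu(Lg.t()), z);
  }

  // Recompute S = e' K^-1 e for the current K.
  void sync_S(const arma::vec& e) {
    arma::vec we = arma::solve(arma::trimatl(Lk), e);
    S_cur = arma::dot(we, we);
  }

  // Gibbs draw of sigma2_P: scaled inverse chi-square implied by the flat
  // positive prior, shape n/2 - 1, scale S/2.
  void update_sigma2() {
    double shape = 0.5 * n - 1.0;
    double g = R::rgamma(shape, 1.0);
    if (g <= 0.0) g = 1e-300;
    s2 = (0.5 * S_cur) / g;
  }

  double logpost() const { return -0.5 * logdetK - S_cur / (2.0 * s2); }

  // Reflected random-walk Metropolis update of ratio j.
  bool mh_ratio(int j, const arma::vec& e, double step) {
    double b = 1.0 - (arma::accu(r) - r(j));
    if (b < 1e-12) return false;
    double prop = reflect_interval(r(j) + step * R::norm_rand(), 0.0, b);
    arma::mat Kp = K + (prop - r(j)) * kernel(j);
    Kp.diag() -= (prop - r(j));
    arma::mat Lp;
    if (!arma::chol(Lp, Kp, "lower")) return false;
    arma::vec we = arma::solve(arma::trimatl(Lp), e);
    double Sp = arma::dot(we, we);
    double logdetp = 2.0 * arma::accu(arma::log(Lp.diag()));
    double lp_prop = -0.5 * logdetp - Sp / (2.0 * s2);
    double lp_cur = logpost();
    if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
      r(j) = prop;
      K = Kp; Lk = Lp; logdetK = logdetp; S_cur = Sp;
      return true;
    }
    return false;
  }

  // Log of the normalized conditional posterior density of ratio j at
  // zero, given the current draws of everything else.  Simpson's rule on
  // grid_size points over the conditional support [0, 1 - sum(others)];
  // the density is zero beyond the support, so this normalization equals
  // normalization over [0, 1].
  double log_dens0(int j, const arma::vec& e, int grid_size) {
    double b = 1.0 - (arma::accu(r) - r(j));
    if (b < 1e-10) return NA_REAL;
    arma::mat Nj = kernel(j);
    Nj.diag() -= 1.0;
    arma::mat W = arma::solve(arma::trimatl(Lk), Nj);
    arma::mat B = arma::solve(arma::trimatl(Lk), W.t()).t();
    B = 0.5 * (B + B.t());
    arma::vec d;
    arma::mat Q;
    if (!arma::eig_sym(d, Q, B)) return NA_REAL;
    arma::vec w = arma::solve(arma::trimatl(Lk), e);
    arma::vec z2 = arma::square(Q.t() * w);
    int G = grid_size;
    arma::vec glog(G);
    double h = b / (G - 1);
    for (int k = 0; k < G; ++k) {
      double t = (k == G - 1) ? b : k * h;
      arma::vec fac = 1.0 + (t - r(j)) * d;
      if (fac.min() <= 1e-12) { glog(k) = R_NegInf; continue; }
      glog(k) = -0.5 * arma::accu(arma::log(fac))
                - arma::accu(z2 / fac) / (2.0 * s2);
    }
    double m = glog.max();
    if (!std::isfinite(m)) return NA_REAL;
    double acc = 0.0;
    for (int k = 0; k < G; ++k) {
      double wk = (k == 0 || k == G - 1) ? 1.0 : ((k % 2 == 1) ? 4.0 : 2.0);
      if (std::isfinite(glog(k))) acc += wk * std::exp(glog(k) - m);
    }
    double logI = std::log(acc * h / 3.0);
    return glog(0) - m - logI;
  }

  double deviance(double two_pi_term) const {
    // -2 log MVN(e; 0, s2 * K); two_pi_term = n * log(2*pi)
    return two_pi_term + n * std::log(s2) + logdetK + S_cur / s2;
  }
};

static void adapt_step(double& step, int& acc, int window, double lo, double hi) {
  double rate = (double)acc / window;
  if (rate < lo) step *= 0.7;
  else if (rate > hi) step *= 1.3;
  if (step < 1e-4) step = 1e-4;
  acc = 0;
}

// [[Rcpp::export]]
List chain_lmm_cpp(const arma::vec& y, const arma::mat& X,
                   const arma::mat& Ka, const arma::mat& Kl, const arma::mat& Kc,
                   int n_iter, int burnin, arma::vec step, int grid_size,
                   bool density_grid, const LogicalVector& update_ratio,
                   bool adapt, arma::vec r_init, double s2_init,
                   arma::vec beta_init) {
  int n = y.n_elem, p = X.n_cols;
  SecondStage st(Ka, Kl, Kc, X, beta_init, r_init, s2_init);
  int kept = n_iter - burnin;
  arma::mat ratios(kept, 3), betas(kept, std::max(p, 1)), logd0(kept, 3);
  arma::vec sig2(kept), dev(kept);
  logd0.fill(NA_REAL);
  int acc[3] = {0, 0, 0};
  arma::vec acc_total(3, arma::fill::zeros), try_total(3, arma::fill::zeros);
  double two_pi_term = n * std::log(2.0 * M_PI);
  const int window = 50;

  for (int it = 1; it <= n_iter; ++it) {
    st.update_beta(y);
    arma::vec e = (p > 0) ? arma::vec(y - X * st.beta) : y;
    st.sync_S(e);
    st.update_sigma2();
    for (int j = 0; j < 3; ++j) {
      if (!update_ratio[j]) continue;
      bool a = st.mh_ratio(j, e, step(j));
      if (a) acc[j]++;
      if (it > burnin) { try_total(j) += 1.0; acc_total(j) += a ? 1.0 : 0.0; }
    }
    if (adapt && it <= burnin && it % window == 0)
      for (int j = 0; j < 3; ++j)
        if (update_ratio[j]) adapt_step(step(j), acc[j], window, 0.20, 0.45);
    if (it > burnin) {
      int k = it - burnin - 1;
      if (density_grid)
        for (int j = 0; j < 3; ++j)
          if (update_ratio[j]) logd0(k, j) = st.log_dens0(j, e, grid_size);
      ratios.row(k) = st.r.t();
      sig2(k) = st.s2;
      if (p > 0) betas.row(k) = st.beta.t();
      dev(k) = st.deviance(two_pi_term);
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["ratios"] = ratios, _["sigma2"] = sig2,
    _["beta"] = (p > 0) ? betas : arma::mat(kept, 0),
    _["deviance"] = dev, _["log_dens0"] = logd0,
    _["accept"] = acc_total / arma::clamp(try_total, 1.0, arma::datum::inf),
    _["step"] = step);
}

// Marginal (population-focus) ZIP deviance: lambda* integrated out
// observation-wise by Gauss-Hermite quadrature against its second-stage
// normal, N(mu_i, sd_i^2).
static double zip_marginal_deviance(const arma::vec& y, const arma::vec& mu,
                                    const arma::vec& sdv, double pstar,
                                    const arma::vec& gh_x, const arma::vec& gh_logw) {
  int n = y.n_elem, q = gh_x.n_elem;
  double dev = 0.0;
  double lc = -log1pexp_d(pstar);
  for (int i = 0; i < n; ++i) {
    double m = R_NegInf;
    arma::vec terms(q);
    for (int k = 0; k < q; ++k) {
      double ls = mu(i) + M_SQRT2 * sdv(i) * gh_x(k);
      double t = gh_logw(k) + zip_obs_term(y(i), ls, pstar);
      if (y(i) > 0) t -= std::lgamma(y(i) + 1.0);
      terms(k) = t;
      if (t > m) m = t;
    }
    double acc = 0.0;
    for (int k = 0; k < q; ++k)
      if (std::isfinite(terms(k))) acc += std::exp(terms(k) - m);
    dev += -2.0 * (lc + m + std::log(acc) - 0.5 * std::log(M_PI));
  }
  return dev;
}

// [[Rcpp::export]]
double zip_loglik_cpp(const arma::vec& y, const arma::vec& lamstar, double pstar) {
  int n = y.n_elem;
  double ll = 0.0, lc = -log1pexp_d(pstar);
  for (int i = 0; i < n; ++i) {
    ll += lc + zip_obs_term(y(i), lamstar(i), pstar);
    if (y(i) > 0) ll -= std::lgamma(y(i) + 1.0);
  }
  return ll;
}

// [[Rcpp::export]]
List chain_zip_cpp(const arma::vec& y, const arma::mat& X,
                   const arma::mat& Ka, const arma::mat& Kl, const arma::mat& Kc,
                   int n_iter, int burnin, arma::vec step, double step_lam,
                   double step_pstar, int grid_size, bool density_grid,
                   const LogicalVector& update_ratio, bool adapt,
                   arma::vec r_init, double s2_init, arma::vec beta_init,
                   arma::vec lamstar_init, double pstar_init,
                   const arma::vec& gh_x, const arma::vec& gh_logw) {
  int n = y.n_elem, p = X.n_cols;
  SecondStage st(Ka, Kl, Kc, X, beta_init, r_init, s2_init);
  arma::vec lamstar = lamstar_init;
  double pstar = pstar_init;
  int kept = n_iter - burnin;
  arma::mat ratios(kept, 3), betas(kept, std::max(p, 1)), logd0(kept, 3);
  arma::vec sig2(kept), dev_cond(kept), dev_marg(kept), pstars(kept);
  arma::vec lamstar_sum(n, arma::fill::zeros);
  logd0.fill(NA_REAL);
  int acc[3] = {0, 0, 0}, acc_lam = 0, acc_p = 0;
  long acc_lam_post = 0, acc_p_post = 0;
  arma::vec acc_total(3, arma::fill::zeros), try_total(3, arma::fill::zeros);
  double acc_lam_total = 0.0, acc_p_total = 0.0;
  const int window = 50;

  for (int it = 1; it <= n_iter; ++it) {
    // --- data level: elementwise MH on lambda* ---
    arma::vec mu = (p > 0) ? arma::vec(X * st.beta) : arma::vec(n, arma::fill::zeros);
    arma::mat Linv = arma::inv(arma::trimatl(st.Lk));
    arma::mat Omega = (Linv.t() * Linv) / st.s2;  // V^-1
    arma::vec rv = Omega * (lamstar - mu);
    for (int i = 0; i < n; ++i) {
      double oii = Omega(i, i);
      double vi = 1.0 / oii;
      double mi = lamstar(i) - rv(i) * vi;
      double cur = lamstar(i);
      double prop = cur + step_lam * R::norm_rand();
      double dl = zip_obs_term(y(i), prop, pstar) - zip_obs_term(y(i), cur, pstar)
        - (prop - mi) * (prop - mi) / (2.0 * vi)
        + (cur - mi) * (cur - mi) / (2.0 * vi);
      if (std::log(R::unif_rand()) < dl) {
        lamstar(i) = prop;
        rv += (prop - cur) * Omega.col(i);
        acc_lam++;
        if (it > burnin) acc_lam_post++;
      }
    }
    // --- population level: reflected MH on p* in [-5, 5] ---
    {
      double prop = reflect_interval(pstar + step_pstar * R::norm_rand(), -5.0, 5.0);
      double dl = n * (log1pexp_d(pstar) - log1pexp_d(prop));
      for (int i = 0; i < n; ++i) {
        if (y(i) != 0.0) continue;
        double lam = (lamstar(i) < 690.0) ? std::exp(lamstar(i)) : R_PosInf;
        dl += logsumexp2(prop, -lam) - logsumexp2(pstar, -lam);
      }
      if (std::log(R::unif_rand()) < dl) { pstar = prop; acc_p++; if (it > burnin) acc_p_post++; }
    }
    // --- second stage on lambda* ---
    st.update_beta(lamstar);
    arma::vec e = (p > 0) ? arma::vec(lamstar - X * st.beta) : lamstar;
    st.sync_S(e);
    st.update_sigma2();
    for (int j = 0; j < 3; ++j) {
      if (!update_ratio[j]) continue;
      bool a = st.mh_ratio(j, e, step(j));
      if (a) acc[j]++;
      if (it > burnin) { try_total(j) += 1.0; acc_total(j) += a ? 1.0 : 0.0; }
    }
    if (adapt && it <= burnin && it % window == 0) {
      for (int j = 0; j < 3; ++j)
        if (update_ratio[j]) adapt_step(step(j), acc[j], window, 0.20, 0.45);
      double rate = (double)acc_lam / (window * n);
      if (rate < 0.20) step_lam *= 0.7; else if (rate > 0.45) step_lam *= 1.3;
      acc_lam = 0;
      adapt_step(step_pstar, acc_p, window, 0.20, 0.45);
    }
    if (it > burnin) {
      int k = it - burnin - 1;
      if (density_grid)
        for (int j = 0; j < 3; ++j)
          if (update_ratio[j]) logd0(k, j) = st.log_dens0(j, e, grid_size);
      ratios.row(k) = st.r.t();
      sig2(k) = st.s2;
      if (p > 0) betas.row(k) = st.beta.t();
      pstars(k) = pstar;
      lamstar_sum += lamstar;
      dev_cond(k) = -2.0 * zip_loglik_cpp(y, lamstar, pstar);
      arma::vec mu2 = (p > 0) ? arma::vec(X * st.beta) : arma::vec(n, arma::fill::zeros);
      arma::vec sdv = arma::sqrt(st.s2 * st.K.diag());
      dev_marg(k) = zip_marginal_deviance(y, mu2, sdv, pstar, gh_x, gh_logw);
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  acc_lam_total = (double)acc_lam_post / std::max(1, n_iter - burnin) / n;
  acc_p_total = (double)acc_p_post / std::max(1, n_iter - burnin);
  return List::create(
    _["ratios"] = ratios, _["sigma2"] = sig2,
    _["beta"] = (p > 0) ? betas : arma::mat(kept, 0),
    _["pstar"] = pstars,
    _["deviance"] = dev_cond, _["deviance_marginal"] = dev_marg,
    _["log_dens0"] = logd0,
    _["lamstar_mean"] = lamstar_sum / kept,
    _["accept"] = acc_total / arma::clamp(try_total, 1.0, arma::datum::inf),
    _["accept_lamstar"] = acc_lam_total, _["accept_pstar"] = acc_p_total,
    _["step"] = step, _["step_lam"] = step_lam, _["step_pstar"] = step_pstar);
}

// [[Rcpp::export]]
double zip_marginal_deviance_cpp(const arma::vec& y, const arma::vec& mu,
                                 const arma::vec& sdv, double pstar,
                                 const arma::vec& gh_x, const arma::vec& gh_logw) {
  return zip_marginal_deviance(y, mu, sdv, pstar, gh_x, gh_logw);
}
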