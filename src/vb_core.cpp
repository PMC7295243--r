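// Core coordinate-ascent variational updates for the hierarchical
// spike-and-slab multi-trait regression.
//
// Model (per trait t = 1..q, SNP s = 1..p):
//   y_t | beta_t, tau_t ~ N(X beta_t, tau_t^{-1} I)   (observed entries only)
//   beta_st | gamma_st = 1 ~ N(0, sigma^2 / tau_t),  gamma_st ~ Bern(omega_s)
//   omega_s ~ Beta(a_s, b_s),  tau_t ~ Gamma(eta_t, kappa_t),
//   sigma^{-2} ~ Gamma(lambda, nu)
//
// The factorized posterior is q(beta,gamma) q(omega) q(tau) q(sigma^{-2}).
// Annealing tempers the likelihood: at temperature T the objective is
//   F_T = (1/T) E_q[log p(y | .)] + E_q[log p(parameters)] + H(q),
// so hot sweeps stay close to the (sparse) prior and associations switch on
// strongest-first as T decreases; T = 1 recovers the usual evidence lower
// bound and its monotone coordinate-ascent sweeps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);
static const double LOGIT_CLIP = 35.0;  // guard before the logistic transform

static const uword VB_BLOCK = 64;  // SNP block width for BLAS-based sweeps

struct VBData {
  const mat& X;        // n x p centered dosages
  const mat& Y0;       // n x q traits, zero-filled at missing entries
  const mat& M;        // n x q observation mask (0/1)
  bool any_missing;
  vec nobs;            // per-trait observed count
  vec xtx_full;        // p: x_s' x_s on all samples (full-data fast path)
  mat xtx_m;           // p x q: per-trait masked x_s' x_s (only if missing)
  std::vector<bool> trait_missing;
  std::vector<mat> gram;  // per-block X_b' X_b (full-data traits)

  VBData(const mat& X_, const mat& Y0_, const mat& M_, bool any_missing_)
    : X(X_), Y0(Y0_), M(M_), any_missing(any_missing_) {
    nobs = sum(M, 0).t();
    xtx_full = sum(square(X), 0).t();
    trait_missing.resize(Y0.n_cols);
    bool need_gram = false;
    if (any_missing) {
      xtx_m = square(X).t() * M;
      for (uword t = 0; t < Y0.n_cols; ++t) {
        trait_missing[t] = (nobs(t) < (double) X.n_rows);
        if (!trait_missing[t]) need_gram = true;
      }
    } else {
      for (uword t = 0; t < Y0.n_cols; ++t) trait_missing[t] = false;
      need_gram = true;
    }
    if (need_gram) {
      const uword p = X.n_cols;
      for (uword a = 0; a < p; a += VB_BLOCK) {
        uword e = std::min(a + VB_BLOCK, p) - 1;
        gram.push_back(X.cols(a, e).t() * X.cols(a, e));
      }
    }
  }
  inline double xtx(uword s, uword t) const {
    return any_missing ? xtx_m(s, t) : xtx_full(s);
  }
};

struct VBState {
  mat g, mu, s2;              // p x q spike-and-slab factors
  vec wa, wb;                 // p: Beta posterior of omega_s
  vec tshape, trate;          // q: Gamma posterior of tau_t
  double sshape, srate;       // Gamma posterior of sigma^{-2}
  mat R;                      // n x q masked residual M o (Y - X (g o mu))
  // cached expectations
  vec Etau, Elogtau, Elogw, Elog1mw;
  double Esig, Elogsig;
  // per-sweep sufficient statistics reused by the ELBO
  vec Ers, Sg, Sm;            // q: E residual SS; sum_s g; sum_s g(mu^2+s2)
};

struct VBHyper {
  vec a_s, b_s;               // p
  vec eta, kappa;             // q
  double lambda, nu;
  bool fix_tau, fix_sigma, fix_omega;
  vec tau_fixed;              // q (if fix_tau)
  double sig_fixed;           // sigma^{-2} (if fix_sigma)
  vec omega_fixed;            // p (if fix_omega)
};

static void refresh_expectations(VBState& st, const VBHyper& hy) {
  const uword p = st.g.n_rows, q = st.g.n_cols;
  if (hy.fix_tau) {
    st.Etau = hy.tau_fixed;
    st.Elogtau = log(hy.tau_fixed);
  } else {
    st.Etau = st.tshape / st.trate;
    st.Elogtau.set_size(q);
    for (uword t = 0; t < q; ++t)
      st.Elogtau(t) = R::digamma(st.tshape(t)) - std::log(st.trate(t));
  }
  if (hy.fix_sigma) {
    st.Esig = hy.sig_fixed;
    st.Elogsig = std::log(hy.sig_fixed);
  } else {
    st.Esig = st.sshape / st.srate;
    st.Elogsig = R::digamma(st.sshape) - std::log(st.srate);
  }
  st.Elogw.set_size(p); st.Elog1mw.set_size(p);
  if (hy.fix_omega) {
    st.Elogw = log(hy.omega_fixed);
    st.Elog1mw = log(1.0 - hy.omega_fixed);
  } else {
    for (uword s = 0; s < p; ++s) {
      double dab = R::digamma(st.wa(s) + st.wb(s));
      st.Elogw(s) = R::digamma(st.wa(s)) - dab;
      st.Elog1mw(s) = R::digamma(st.wb(s)) - dab;
    }
  }
}

// One full pass: all (beta_st, gamma_st) blocks (traits outer, SNPs inner,
// with running residuals), then the conjugate omega, tau, sigma^{-2}
// updates. The likelihood contributions carry weight 1/T.
static void sweep_once(VBState& st, const VBData& dat, const VBHyper& hy,
                       double T) {
  const uword n = dat.X.n_rows, p = dat.X.n_cols, q = dat.Y0.n_cols;
  const double invT = 1.0 / T;

  for (uword t = 0; t < q; ++t) {
    double* r = st.R.colptr(t);
    const double* m = dat.M.colptr(t);
    const bool tmiss = dat.trait_missing[t];
    const double etau = st.Etau(t);
    const double elogtau = st.Elogtau(t);

    // one (beta_st, gamma_st) coordinate update; xr is the partial-residual
    // inner product x_s' (y_t - sum_{s' != s} b_{s't} x_{s'})
    auto update_pair = [&](uword s, double xr, double b_old) -> double {
      const double xtx_st = dat.xtx(s, t);
      const double prec = etau * (invT * xtx_st + st.Esig);
      const double s2_new = 1.0 / prec;
      const double mu_new = invT * etau * xr / prec;
      double u = st.Elogw(s) - st.Elog1mw(s)
                 + 0.5 * (st.Elogsig + elogtau)
                 + 0.5 * std::log(s2_new)
                 + mu_new * mu_new / (2.0 * s2_new);
      if (u > LOGIT_CLIP) u = LOGIT_CLIP;
      if (u < -LOGIT_CLIP) u = -LOGIT_CLIP;
      const double g_new = 1.0 / (1.0 + std::exp(-u));
      if (!std::isfinite(mu_new) || !std::isfinite(g_new))
        Rcpp::stop("non-finite variational update at SNP %d, trait %d",
                   (int) s + 1, (int) t + 1);
      st.g(s, t) = g_new;
      st.mu(s, t) = mu_new;
      st.s2(s, t) = s2_new;
      return b_old - g_new * mu_new;  // residual correction coefficient
    };

    if (tmiss) {  // masked trait: plain sequential loop on masked residuals
      for (uword s = 0; s < p; ++s) {
        const double* x = dat.X.colptr(s);
        const double b_old = st.g(s, t) * st.mu(s, t);
        // masked rows of R are exactly zero, so the plain dot product is
        // the inner product over this trait's observed samples
        double xr = dot(dat.X.col(s), st.R.col(t)) + b_old * dat.xtx(s, t);
        const double d = update_pair(s, xr, b_old);
        if (d != 0.0)
          for (uword i = 0; i < n; ++i) r[i] += d * x[i] * m[i];
      }
    } else {
      // blocked sweep: identical to the sequential update order, but the
      // residual inner products of a whole SNP block are taken in one BLAS
      // product and corrected within the block via its Gram matrix
      vec rv(r, n, false, true);
      for (uword b = 0, a = 0; a < p; ++b, a += VB_BLOCK) {
        const uword e = std::min(a + VB_BLOCK, p) - 1;
        const uword L = e - a + 1;
        vec xr0 = dat.X.cols(a, e).t() * rv;
        const mat& Gb = dat.gram[b];
        vec dvec(L, fill::zeros);
        bool any_d = false;
        for (uword j = 0; j < L; ++j) {
          const uword s = a + j;
          const double b_old = st.g(s, t) * st.mu(s, t);
          double xr = xr0(j) + b_old * dat.xtx(s, t);
          for (uword j2 = 0; j2 < j; ++j2)
            if (dvec(j2) != 0.0) xr += dvec(j2) * Gb(j2, j);
          dvec(j) = update_pair(s, xr, b_old);
          if (dvec(j) != 0.0) any_d = true;
        }
        if (any_d) rv += dat.X.cols(a, e) * dvec;
      }
    }
  }

  // sweep statistics
  st.Sg = sum(st.g, 0).t();
  mat gm2 = st.g % (square(st.mu) + st.s2);
  st.Sm = sum(gm2, 0).t();
  st.Ers.set_size(q);
  for (uword t = 0; t < q; ++t) {
    double extra = 0.0;
    for (uword s = 0; s < p; ++s) {
      double b = st.g(s, t) * st.mu(s, t);
      extra += dat.xtx(s, t) * (gm2(s, t) - b * b);
    }
    st.Ers(t) = dot(st.R.col(t), st.R.col(t)) + extra;
  }

  // conjugate updates: omega, then tau (likelihood part weighted 1/T),
  // then sigma^{-2}
  if (!hy.fix_omega) {
    vec rg = sum(st.g, 1);
    st.wa = hy.a_s + rg;
    st.wb = hy.b_s + ((double) q) - rg;
  }
  if (!hy.fix_tau) {
    for (uword t = 0; t < q; ++t) {
      st.tshape(t) = hy.eta(t) + 0.5 * invT * dat.nobs(t) + 0.5 * st.Sg(t);
      st.trate(t) = hy.kappa(t) + 0.5 * invT * st.Ers(t)
                    + 0.5 * st.Esig * st.Sm(t);
    }
    st.Etau = st.tshape / st.trate;
    for (uword t = 0; t < q; ++t)
      st.Elogtau(t) = R::digamma(st.tshape(t)) - std::log(st.trate(t));
  }
  if (!hy.fix_sigma) {
    st.sshape = hy.lambda + 0.5 * accu(st.Sg);
    st.srate = hy.nu + 0.5 * dot(st.Etau, st.Sm);
    st.Esig = st.sshape / st.srate;
    st.Elogsig = R::digamma(st.sshape) - std::log(st.srate);
  }
  if (!hy.fix_omega) {
    for (uword s = 0; s < p; ++s) {
      double dab = R::digamma(st.wa(s) + st.wb(s));
      st.Elogw(s) = R::digamma(st.wa(s)) - dab;
      st.Elog1mw(s) = R::digamma(st.wb(s)) - dab;
    }
  }
}

static double gamma_entropy(double shape, double rate) {
  return shape - std::log(rate) + std::lgamma(shape)
         + (1.0 - shape) * R::digamma(shape);
}

static double beta_entropy(double a, double b) {
  return R::lbeta(a, b) - (a - 1.0) * R::digamma(a)
         - (b - 1.0) * R::digamma(b) + (a + b - 2.0) * R::digamma(a + b);
}

// F_T = (1/T) E_q[log p(y|.)] + E_q[log p(parameters)] + H(q); point-mass
// terms of the Dirac spike cancel between E log p and the entropy and are
// omitted on both sides.
static double objective(const VBState& st, const VBData& dat,
                        const VBHyper& hy, double T) {
  const uword p = st.g.n_rows, q = st.g.n_cols;
  double elogp = 0.0;

  for (uword t = 0; t < q; ++t) {
    elogp += (0.5 * dat.nobs(t) * (st.Elogtau(t) - LOG2PI)
              - 0.5 * st.Etau(t) * st.Ers(t)) / T;
    elogp += 0.5 * (st.Elogsig + st.Elogtau(t) - LOG2PI) * st.Sg(t)
             - 0.5 * st.Esig * st.Etau(t) * st.Sm(t);
  }
  vec rg = sum(st.g, 1);
  for (uword s = 0; s < p; ++s) {
    elogp += rg(s) * st.Elogw(s) + ((double) q - rg(s)) * st.Elog1mw(s);
    if (!hy.fix_omega)
      elogp += (hy.a_s(s) - 1.0) * st.Elogw(s)
               + (hy.b_s(s) - 1.0) * st.Elog1mw(s)
               - R::lbeta(hy.a_s(s), hy.b_s(s));
  }
  if (!hy.fix_tau)
    for (uword t = 0; t < q; ++t)
      elogp += hy.eta(t) * std::log(hy.kappa(t)) - std::lgamma(hy.eta(t))
               + (hy.eta(t) - 1.0) * st.Elogtau(t)
               - hy.kappa(t) * st.Etau(t);
  if (!hy.fix_sigma)
    elogp += hy.lambda * std::log(hy.nu) - std::lgamma(hy.lambda)
             + (hy.lambda - 1.0) * st.Elogsig - hy.nu * st.Esig;

  double H = 0.0;
  for (uword t = 0; t < q; ++t) {
    for (uword s = 0; s < p; ++s) {
      double gg = st.g(s, t);
      if (gg > 0.0 && gg < 1.0)
        H += -gg * std::log(gg) - (1.0 - gg) * std::log(1.0 - gg);
      H += gg * 0.5 * std::log(2.0 * M_PI * M_E * st.s2(s, t));
    }
  }
  if (!hy.fix_omega)
    for (uword s = 0; s < p; ++s) H += beta_entropy(st.wa(s), st.wb(s));
  if (!hy.fix_tau)
    for (uword t = 0; t < q; ++t) H += gamma_entropy(st.tshape(t), st.trate(t));
  if (!hy.fix_sigma) H += gamma_entropy(st.sshape, st.srate);

  return elogp + H;
}

static VBHyper make_hyper(const vec& a_s, const vec& b_s, const vec& eta,
                          const vec& kappa, double lambda, double nu,
                          bool fix_tau, const vec& tau_fixed, bool fix_sigma,
                          double sig_fixed, bool fix_omega,
                          const vec& omega_fixed) {
  VBHyper hy;
  hy.a_s = a_s; hy.b_s = b_s; hy.eta = eta; hy.kappa = kappa;
  hy.lambda = lambda; hy.nu = nu;
  hy.fix_tau = fix_tau; hy.fix_sigma = fix_sigma; hy.fix_omega = fix_omega;
  hy.tau_fixed = tau_fixed; hy.sig_fixed = sig_fixed;
  hy.omega_fixed = omega_fixed;
  return hy;
}

// Initial factors: q(tau_t) at its null-model posterior and q(sigma^-2) at
// unit scale with one pseudo-observation. Starting instead from the diffuse
// priors themselves would put E[log tau] and E[log sigma^-2] near
// digamma(0.01) ~ -100, an inclusion penalty so large that the all-null
// configuration becomes an absorbing fixed point.
static VBState make_state(const mat& g0, const mat& mu0, const VBData& dat,
                          const VBHyper& hy) {
  VBState st;
  st.g = g0; st.mu = mu0;
  st.s2 = mat(g0.n_rows, g0.n_cols, fill::ones);
  st.wa = hy.a_s; st.wb = hy.b_s;
  vec ssy = sum(square(dat.Y0), 0).t();
  st.tshape = hy.eta + 0.5 * dat.nobs;
  st.trate = hy.kappa + 0.5 * ssy;
  st.sshape = hy.lambda + 1.0; st.srate = hy.nu + 1.0;
  st.R = dat.M % (dat.Y0 - dat.X * (st.g % st.mu));
  refresh_expectations(st, hy);
  return st;
}

static Rcpp::List state_out(const VBState& st, const std::vector<double>& obj,
                            const std::vector<double>& temps, int n_cold,
                            bool converged) {
  return Rcpp::List::create(
    Rcpp::Named("g") = st.g,
    Rcpp::Named("mu") = st.mu,
    Rcpp::Named("s2") = st.s2,
    Rcpp::Named("omega_a") = st.wa,
    Rcpp::Named("omega_b") = st.wb,
    Rcpp::Named("tau_shape") = st.tshape,
    Rcpp::Named("tau_rate") = st.trate,
    Rcpp::Named("sigma2inv_shape") = st.sshape,
    Rcpp::Named("sigma2inv_rate") = st.srate,
    Rcpp::Named("objective") = obj.empty() ? NA_REAL : obj.back(),
    Rcpp::Named("trace_objective") = obj,
    Rcpp::Named("trace_temperature") = temps,
    Rcpp::Named("n_sweeps_cold") = n_cold,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export(name = ".vb_fit_cpp")]]
Rcpp::List vb_fit_cpp(const arma::mat& X, const arma::mat& Y0,
                      const arma::mat& M, bool any_missing,
                      const arma::mat& g0, const arma::mat& mu0,
                      const arma::vec& a_s, const arma::vec& b_s,
                      const arma::vec& eta, const arma::vec& kappa,
                      double lambda, double nu,
                      const arma::vec& schedule, double tol, int max_iter,
                      bool fix_tau, const arma::vec& tau_fixed,
                      bool fix_sigma, double sig_fixed,
                      bool fix_omega, const arma::vec& omega_fixed) {
  VBData dat(X, Y0, M, any_missing);
  VBHyper hy = make_hyper(a_s, b_s, eta, kappa, lambda, nu, fix_tau, tau_fixed,
                          fix_sigma, sig_fixed, fix_omega, omega_fixed);
  VBState st = make_state(g0, mu0, dat, hy);

  std::vector<double> obj, temps;
  // hot rungs: one sweep each; the last scheduled rung must be T = 1
  for (uword k = 0; k < schedule.n_elem; ++k) {
    double T = schedule(k);
    sweep_once(st, dat, hy, T);
    obj.push_back(objective(st, dat, hy, T));
    temps.push_back(T);
  }
  // convergence-checked sweeps at T = 1
  bool converged = false;
  int n_cold = (schedule.n_elem > 0 && schedule(schedule.n_elem - 1) == 1.0)
                 ? 1 : 0;
  double prev = (n_cold == 1) ? obj.back() : NA_REAL;
  for (int it = 0; it < max_iter; ++it) {
    sweep_once(st, dat, hy, 1.0);
    double cur = objective(st, dat, hy, 1.0);
    obj.push_back(cur);
    temps.push_back(1.0);
    ++n_cold;
    if (std::isfinite(prev) && std::fabs(cur - prev) < tol) {
      converged = true;
      break;
    }
    prev = cur;
  }
  return state_out(st, obj, temps, n_cold, converged);
}

// Single tempered sweep from an explicit state; used to test the update
// operator itself (monotonicity, batched-vs-sequential agreement).
// [[Rcpp::export(name = ".vb_sweep_cpp")]]
Rcpp::List vb_sweep_cpp(const arma::mat& X, const arma::mat& Y0,
                        const arma::mat& M, bool any_missing,
                        const arma::mat& g, const arma::mat& mu,
                        const arma::mat& s2,
                        const arma::vec& wa, const arma::vec& wb,
                        const arma::vec& tshape, const arma::vec& trate,
                        double sshape, double srate,
                        const arma::vec& a_s, const arma::vec& b_s,
                        const arma::vec& eta, const arma::vec& kappa,
                        double lambda, double nu, double temperature,
                        bool fix_tau, const arma::vec& tau_fixed,
                        bool fix_sigma, double sig_fixed,
                        bool fix_omega, const arma::vec& omega_fixed) {
  if (temperature < 1.0) Rcpp::stop("temperature must be >= 1");
  VBData dat(X, Y0, M, any_missing);
  VBHyper hy = make_hyper(a_s, b_s, eta, kappa, lambda, nu, fix_tau, tau_fixed,
                          fix_sigma, sig_fixed, fix_omega, omega_fixed);
  VBState st;
  st.g = g; st.mu = mu; st.s2 = s2;
  st.wa = wa; st.wb = wb; st.tshape = tshape; st.trate = trate;
  st.sshape = sshape; st.srate = srate;
  st.R = dat.M % (dat.Y0 - dat.X * (st.g % st.mu));
  refresh_expectations(st, hy);
  sweep_once(st, dat, hy, temperature);
  std::vector<double> obj(1, objective(st, dat, hy, temperature));
  std::vector<double> temps(1, temperature);
  return state_out(st, obj, temps, 0, false);
}
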