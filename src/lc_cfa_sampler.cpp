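// Gibbs sampler for the two-class latent-class CFA mixture.
//
// Class 1: y_ij ~ F(g^-1(tau1_j + lambda_j eta_{i,f(j)}), sigma2_1j),
//          eta_i ~ MVN(0, Phi), scaling loading per factor fixed to 1.
// Class 2: y_ij ~ F(g^-1(tau2_j), sigma2_2j)  (intercept-only random response).
// P(C_i = 1) = expit(beta0 + beta1 y1_i + beta2 y2_i).
//
// Continuous family: all conditionals conjugate (normal / truncated normal /
// gamma / Wishart); beta updated by independence MH from a Laplace
// multivariate-t approximation of its conditional posterior.
// Binary (logit) and count (log) families: eta, tau, lambda updated by
// adaptive random-walk Metropolis; C and Phi remain exact draws.
//
// Uses R's RNG throughout so chains replay under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rnorm1() { return R::norm_rand(); }

// N(mu, s^2) truncated to [0, Inf)
static double rtnorm_pos(double mu, double s) {
  double alpha = -mu / s;
  if (alpha < 5.0) {
    double plo = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double u = plo + R::unif_rand() * (1.0 - plo);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return mu + s * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  // Robert (1995) exponential rejection for a far-right truncation point
  double a = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double z = alpha + R::exp_rand() / a;
    double rho = std::exp(-0.5 * (z - a) * (z - a));
    if (R::unif_rand() <= rho) return mu + s * z;
  }
}

// Wishart(V, df) via Bartlett decomposition (E[W] = df * V)
static arma::mat rwishart(const arma::mat& V, double df) {
  const int m = V.n_rows;
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(m, m, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static inline double log_expit(double x) {
  return (x > 0.0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

// Laplace approximation of the conditional posterior of the class-model
// coefficients p(beta | C): Newton iterations on the prior-regularized
// logistic log-posterior. Returns the mode and the Hessian at the mode.
static void beta_laplace(const arma::mat& X, const arma::vec& y,
                         double beta_pv, arma::vec& mode, arma::mat& H) {
  const int d = X.n_cols;
  for (int step = 0; step < 50; ++step) {
    arma::vec lin = X * mode;
    arma::vec pr(lin.n_elem), w(lin.n_elem);
    for (arma::uword i = 0; i < lin.n_elem; ++i) {
      pr(i) = 1.0 / (1.0 + std::exp(-lin(i)));
      w(i) = std::max(pr(i) * (1.0 - pr(i)), 1e-10);
    }
    arma::vec grad = X.t() * (y - pr) - mode / beta_pv;
    arma::mat Xw = X;
    Xw.each_col() %= w;
    H = X.t() * Xw + arma::eye(d, d) / beta_pv;
    arma::vec delta = arma::solve(H, grad);
    double nd = arma::norm(delta);
    if (nd > 5.0) delta *= 5.0 / nd;   // damp early steps under separation
    mode += delta;
    if (nd < 1e-8) break;
  }
  // Hessian evaluated at the final mode
  arma::vec lin = X * mode;
  arma::vec w(lin.n_elem);
  for (arma::uword i = 0; i < lin.n_elem; ++i) {
    double pr = 1.0 / (1.0 + std::exp(-lin(i)));
    w(i) = std::max(pr * (1.0 - pr), 1e-10);
  }
  arma::mat Xw = X;
  Xw.each_col() %= w;
  H = X.t() * Xw + arma::eye(d, d) / beta_pv;
}

// log f(y_ij | linear predictor x, sigma2) for one cell
static inline double cell_loglik(int family, double y, double x, double s2) {
  if (family == 0) {            // continuous / identity
    double r = y - x;
    return -0.5 * (std::log(2.0 * M_PI * s2) + r * r / s2);
  } else if (family == 1) {     // binary / logit
    return y * x - std::log1p(std::exp(x));
  }
  return y * x - std::exp(x);   // count / log (log y! constant dropped)
}

// [[Rcpp::export]]
List lc_cfa_chain(const arma::mat& Y, const arma::uvec& item_factor,
                  const arma::mat& X, int family, bool mixture,
                  const List& priors, int n_iter, int n_burnin,
                  const List& init) {
  const int N = Y.n_rows, p = Y.n_cols;
  const int m = arma::max(item_factor);
  const arma::uvec fac = item_factor - 1;   // 0-based factor of each item

  // scaling indicator = first mapped item of each factor (loading fixed to 1)
  arma::ivec is_free(p, arma::fill::ones);
  {
    std::vector<bool> seen(m, false);
    for (int j = 0; j < p; ++j) {
      if (!seen[fac(j)]) { seen[fac(j)] = true; is_free(j) = 0; }
    }
  }
  arma::uvec free_idx = arma::find(is_free == 1);
  const int nfree = free_idx.n_elem;

  // priors
  const double tau_pm   = as<double>(priors["tau_mean"]);
  const double tau_pv   = as<double>(priors["tau_var"]);
  const double lam_pv   = as<double>(priors["lambda_var"]);
  const double beta_pv  = as<double>(priors["beta_var"]);
  const double gam_a    = as<double>(priors["gamma_shape"]);
  const double gam_b    = as<double>(priors["gamma_rate"]);
  const arma::mat Psi0  = as<arma::mat>(priors["wishart_scale"]);
  const double   dfPsi  = as<double>(priors["wishart_df"]);
  const arma::mat Psi0_inv = arma::inv_sympd(Psi0);

  // state
  arma::vec lam   = as<arma::vec>(init["lambda"]);   // full p, fixed entries = 1
  arma::vec tau1  = as<arma::vec>(init["tau1"]);
  arma::vec tau2  = as<arma::vec>(init["tau2"]);
  arma::vec s2_1  = as<arma::vec>(init["sigma2_1"]);
  arma::vec s2_2  = as<arma::vec>(init["sigma2_2"]);
  arma::mat Phi   = as<arma::mat>(init["Phi"]);
  arma::vec beta  = as<arma::vec>(init["beta"]);
  arma::mat eta   = as<arma::mat>(init["eta"]);      // N x m
  arma::ivec C    = as<arma::ivec>(init["C"]);       // 1 or 2
  arma::mat Phi_inv = arma::inv_sympd(Phi);

  const bool has_sigma = (family == 0);

  // monitored layout: tau1 | lambda_free | phi lower-tri | [sigma2_1] |
  //                   mixture: tau2 | [sigma2_2] | beta
  int npar = p + nfree + m * (m + 1) / 2 + (has_sigma ? p : 0);
  if (mixture) npar += p + (has_sigma ? p : 0) + 3;
  const int n_keep = n_iter - n_burnin;
  arma::mat draws(n_keep, npar);
  arma::vec pbot_sum(N, arma::fill::zeros);

  // adaptive MH scales (binary / count families only)
  double s_eta = 0.4;
  arma::vec s_lam(p, arma::fill::value(0.2)), s_tau1(p, arma::fill::value(0.2)),
            s_tau2(p, arma::fill::value(0.2));
  long acc_eta = 0, try_eta = 0;
  // scale- and location-ridge moves: step size and acceptance per factor
  arma::vec s_scale(m, arma::fill::value(0.05));
  arma::ivec acc_scale(m, arma::fill::zeros);
  arma::vec s_loc(m, arma::fill::value(0.05));
  arma::ivec acc_loc(m, arma::fill::zeros);
  arma::ivec scaling_item(m);       // item whose loading is fixed to 1
  arma::ivec n_free_fac(m, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    if (is_free(j)) n_free_fac(fac(j))++;
    else scaling_item(fac(j)) = j;
  }
  arma::ivec acc_lam(p, arma::fill::zeros), acc_tau1(p, arma::fill::zeros),
             acc_tau2(p, arma::fill::zeros);
  int batch = 0;

  arma::vec lin = X * beta;                 // class-model linear predictor

  // per-person conditional log-likelihoods given current state
  auto loglik1_person = [&](int i, const arma::rowvec& eta_i) {
    double ll = 0.0;
    for (int j = 0; j < p; ++j) {
      double x = tau1(j) + lam(j) * eta_i(fac(j));
      ll += cell_loglik(family, Y(i, j), x, s2_1(j));
    }
    return ll;
  };
  auto loglik2_person = [&](int i) {
    double ll = 0.0;
    for (int j = 0; j < p; ++j)
      ll += cell_loglik(family, Y(i, j), tau2(j), s2_2(j));
    return ll;
  };

  for (int it = 0; it < n_iter; ++it) {
    // ---- class indicators -------------------------------------------------
    if (mixture) {
      for (int i = 0; i < N; ++i) {
        double l1 = loglik1_person(i, eta.row(i)) + log_expit(lin(i));
        double l2 = loglik2_person(i) + log_expit(-lin(i));
        double p1 = 1.0 / (1.0 + std::exp(l2 - l1));
        C(i) = (R::unif_rand() < p1) ? 1 : 2;
      }
    }
    arma::uvec i1 = arma::find(C == 1), i2 = arma::find(C == 2);
    const int n1 = i1.n_elem, n2 = i2.n_elem;

    // ---- latent factors ---------------------------------------------------
    if (family == 0) {
      // exact: eta_i | C=1 ~ MVN(A^-1 b_i, A^-1), A shared across persons
      arma::mat Lam(p, m, arma::fill::zeros);
      for (int j = 0; j < p; ++j) Lam(j, fac(j)) = lam(j);
      arma::mat LtD = Lam.t();
      LtD.each_row() /= s2_1.t();                    // m x p = Lam' D^-1
      arma::mat A = Phi_inv + LtD * Lam;
      arma::mat SigEta = arma::inv_sympd(A);
      arma::mat Ru = arma::chol(SigEta);             // upper, Ru'Ru = SigEta
      if (n1 > 0) {
        arma::mat R1 = Y.rows(i1);
        R1.each_row() -= tau1.t();
        arma::mat M = R1 * LtD.t() * SigEta;         // n1 x m posterior means
        arma::mat Z(n1, m);
        for (arma::uword r = 0; r < Z.n_rows; ++r)
          for (int c = 0; c < m; ++c) Z(r, c) = rnorm1();
        eta.rows(i1) = M + Z * Ru;
      }
      if (n2 > 0) {
        arma::mat RuP = arma::chol(Phi);
        arma::mat Z(n2, m);
        for (arma::uword r = 0; r < Z.n_rows; ++r)
          for (int c = 0; c < m; ++c) Z(r, c) = rnorm1();
        eta.rows(i2) = Z * RuP;
      }
    } else {
      // MH for class-1 persons, exact prior draw for class-2 persons
      arma::mat RuP = arma::chol(Phi);
      for (int i = 0; i < N; ++i) {
        if (C(i) == 1) {
          arma::rowvec cur = eta.row(i), prop = cur;
          for (int c = 0; c < m; ++c) prop(c) += s_eta * rnorm1();
          double lp_cur = loglik1_person(i, cur) -
            0.5 * arma::as_scalar(cur * Phi_inv * cur.t());
          double lp_new = loglik1_person(i, prop) -
            0.5 * arma::as_scalar(prop * Phi_inv * prop.t());
          ++try_eta;
          if (std::log(R::unif_rand()) < lp_new - lp_cur) {
            eta.row(i) = prop; ++acc_eta;
          }
        } else {
          arma::rowvec z(m);
          for (int c = 0; c < m; ++c) z(c) = rnorm1();
          eta.row(i) = z * RuP;
        }
      }
    }

    // ---- factor covariance ------------------------------------------------
    {
      arma::mat Seta = eta.t() * eta;
      arma::mat V = arma::inv_sympd(Psi0_inv + Seta);
      Phi_inv = rwishart(V, dfPsi + N);
      Phi = arma::inv_sympd(Phi_inv);
    }

    // ---- measurement parameters ------------------------------------------
    if (family == 0) {
      for (int j = 0; j < p; ++j) {
        const int k = fac(j);
        // free loading: truncated-normal conjugate over class-1 persons
        if (is_free(j)) {
          double sxx = 0.0, sxy = 0.0;
          for (int a = 0; a < n1; ++a) {
            int i = i1(a);
            double e = eta(i, k);
            sxx += e * e;
            sxy += e * (Y(i, j) - tau1(j));
          }
          double prec = 1.0 / lam_pv + sxx / s2_1(j);
          double mu = (sxy / s2_1(j)) / prec;
          lam(j) = rtnorm_pos(mu, 1.0 / std::sqrt(prec));
        }
        // class-1 intercept
        {
          double sr = 0.0;
          for (int a = 0; a < n1; ++a) {
            int i = i1(a);
            sr += Y(i, j) - lam(j) * eta(i, k);
          }
          double prec = 1.0 / tau_pv + n1 / s2_1(j);
          double mu = (tau_pm / tau_pv + sr / s2_1(j)) / prec;
          tau1(j) = mu + rnorm1() / std::sqrt(prec);
        }
        // class-1 residual precision
        {
          double ssr = 0.0;
          for (int a = 0; a < n1; ++a) {
            int i = i1(a);
            double r = Y(i, j) - tau1(j) - lam(j) * eta(i, k);
            ssr += r * r;
          }
          double prec = R::rgamma(gam_a + 0.5 * n1, 1.0 / (gam_b + 0.5 * ssr));
          s2_1(j) = 1.0 / prec;
        }
        if (mixture) {
          // class-2 intercept and residual precision
          double sr = 0.0;
          for (int a = 0; a < n2; ++a) sr += Y(i2(a), j);
          double prec = 1.0 / tau_pv + n2 / s2_2(j);
          double mu = (tau_pm / tau_pv + sr / s2_2(j)) / prec;
          tau2(j) = mu + rnorm1() / std::sqrt(prec);
          double ssr = 0.0;
          for (int a = 0; a < n2; ++a) {
            double r = Y(i2(a), j) - tau2(j);
            ssr += r * r;
          }
          double pr2 = R::rgamma(gam_a + 0.5 * n2, 1.0 / (gam_b + 0.5 * ssr));
          s2_2(j) = 1.0 / pr2;
        }
      }
    } else {
      // binary / count: univariate random-walk MH per parameter
      auto item_ll1 = [&](int j, double tau_j, double lam_j) {
        double ll = 0.0;
        const int k = fac(j);
        for (int a = 0; a < n1; ++a) {
          int i = i1(a);
          ll += cell_loglik(family, Y(i, j), tau_j + lam_j * eta(i, k), 1.0);
        }
        return ll;
      };
      auto item_ll2 = [&](int j, double tau_j) {
        double ll = 0.0;
        for (int a = 0; a < n2; ++a)
          ll += cell_loglik(family, Y(i2(a), j), tau_j, 1.0);
        return ll;
      };
      for (int j = 0; j < p; ++j) {
        if (is_free(j)) {
          double prop = lam(j) + s_lam(j) * rnorm1();
          if (prop >= 0.0) {
            double d = item_ll1(j, tau1(j), prop) - item_ll1(j, tau1(j), lam(j)) -
              0.5 * (prop * prop - lam(j) * lam(j)) / lam_pv;
            if (std::log(R::unif_rand()) < d) { lam(j) = prop; acc_lam(j)++; }
          }
        }
        {
          double prop = tau1(j) + s_tau1(j) * rnorm1();
          double d = item_ll1(j, prop, lam(j)) - item_ll1(j, tau1(j), lam(j)) -
            0.5 * ((prop - tau_pm) * (prop - tau_pm) -
                   (tau1(j) - tau_pm) * (tau1(j) - tau_pm)) / tau_pv;
          if (std::log(R::unif_rand()) < d) { tau1(j) = prop; acc_tau1(j)++; }
        }
        if (mixture) {
          double prop = tau2(j) + s_tau2(j) * rnorm1();
          double d = item_ll2(j, prop) - item_ll2(j, tau2(j)) -
            0.5 * ((prop - tau_pm) * (prop - tau_pm) -
                   (tau2(j) - tau_pm) * (tau2(j) - tau_pm)) / tau_pv;
          if (std::log(R::unif_rand()) < d) { tau2(j) = prop; acc_tau2(j)++; }
        }
      }
    }

    // ---- scale-ridge move -------------------------------------------------
    // The factor scale is identified only through the scaling item, so
    // Phi_kk and the free loadings of factor k form a posterior ridge that
    // one-at-a-time Gibbs traverses slowly. A parameter-expansion Metropolis
    // step rescales (eta_k, Phi, lambda_k) jointly along the ridge:
    //   eta_k -> a eta_k, Phi_k. -> a Phi_k., lambda_jk -> lambda_jk / a,
    // which leaves every free item's fit unchanged; only the scaling item's
    // likelihood, the priors and the Jacobian enter the acceptance ratio
    // (the eta prior ratio cancels exactly against the eta Jacobian).
    for (int k = 0; k < m; ++k) {
      const double eps = s_scale(k) * rnorm1();
      const double a = std::exp(eps);
      const int j0 = scaling_item(k);
      double dlp = 0.0;
      // scaling-item likelihood over class-1 persons
      const double s2j0 = has_sigma ? s2_1(j0) : 1.0;
      for (int q = 0; q < n1; ++q) {
        int i = i1(q);
        double e = eta(i, k);
        dlp += cell_loglik(family, Y(i, j0), tau1(j0) + a * e, s2j0) -
               cell_loglik(family, Y(i, j0), tau1(j0) + e, s2j0);
      }
      // free-loading prior (half-normal) ratio and Jacobian a^{-n_free}
      for (int j = 0; j < p; ++j) {
        if (is_free(j) && fac(j) == k) {
          double lj = lam(j), ljn = lj / a;
          dlp += -0.5 * (ljn * ljn - lj * lj) / lam_pv;
        }
      }
      dlp -= n_free_fac(k) * eps;
      // Phi prior ratio (inverse-Wishart in Phi coordinates) and Jacobian:
      // |Phi'| = a^2 |Phi|, Phi'^{-1} = D^{-1} Phi^{-1} D^{-1},
      // row/col-k scaling has Jacobian a^{m+1}
      arma::mat Phi_inv_new = Phi_inv;
      Phi_inv_new.row(k) /= a;
      Phi_inv_new.col(k) /= a;
      dlp += -(dfPsi + m + 1.0) * eps -
        0.5 * (arma::accu(Psi0_inv % Phi_inv_new) -
               arma::accu(Psi0_inv % Phi_inv)) +
        (m + 1.0) * eps;
      if (std::log(R::unif_rand()) < dlp) {
        eta.col(k) *= a;
        Phi.row(k) *= a; Phi.col(k) *= a;
        Phi_inv = Phi_inv_new;
        for (int j = 0; j < p; ++j)
          if (is_free(j) && fac(j) == k) lam(j) /= a;
        acc_scale(k)++;
      }
    }

    // ---- location-ridge move ----------------------------------------------
    // Same idea for the factor location: the mean of eta_k and the
    // intercepts of factor-k items compensate each other. Shift
    //   eta_k -> eta_k + c, tau1_j -> tau1_j - lambda_j c  (items of k),
    // leaving the class-1 likelihood invariant; only the eta and tau priors
    // enter the ratio (shift Jacobian = 1).
    for (int k = 0; k < m; ++k) {
      const double c = s_loc(k) * rnorm1();
      double dlp = 0.0;
      // eta prior: -(1/2) [2 c (sum_i eta_i)' Phi^{-1} e_k + N c^2 (Phi^{-1})_kk]
      arma::rowvec eta_sum = arma::sum(eta, 0);
      dlp += -0.5 * (2.0 * c * arma::dot(eta_sum, Phi_inv.col(k).t()) +
                     N * c * c * Phi_inv(k, k));
      // tau1 prior for mapped items
      for (int j = 0; j < p; ++j) {
        if (fac(j) == (arma::uword) k) {
          double tn = tau1(j) - lam(j) * c;
          dlp += -0.5 * ((tn - tau_pm) * (tn - tau_pm) -
                         (tau1(j) - tau_pm) * (tau1(j) - tau_pm)) / tau_pv;
        }
      }
      if (std::log(R::unif_rand()) < dlp) {
        eta.col(k) += c;
        for (int j = 0; j < p; ++j)
          if (fac(j) == (arma::uword) k) tau1(j) -= lam(j) * c;
        acc_loc(k)++;
      }
    }

    // ---- class-model coefficients -----------------------------------------
    // Independence Metropolis-Hastings from a multivariate-t (df 5)
    // approximation centered at the Laplace mode of p(beta | C). The
    // conditional is low-dimensional and near-Gaussian, so draws are close
    // to independent even under the quasi-separation the indices induce.
    if (mixture) {
      const double t_df = 5.0;
      arma::vec yv(N);
      for (int i = 0; i < N; ++i) yv(i) = (C(i) == 1) ? 1.0 : 0.0;
      arma::vec mode = beta;
      arma::mat H;
      beta_laplace(X, yv, beta_pv, mode, H);
      arma::mat Vl = arma::chol(arma::inv_sympd(H), "lower");
      arma::vec z(3);
      for (int r = 0; r < 3; ++r) z(r) = rnorm1();
      double g = R::rchisq(t_df) / t_df;
      arma::vec prop = mode + (Vl * z) / std::sqrt(g);
      arma::vec lin_new = X * prop;
      auto log_target = [&](const arma::vec& b, const arma::vec& lb) {
        double lp = -0.5 * arma::dot(b, b) / beta_pv;
        for (int i = 0; i < N; ++i)
          lp += (C(i) == 1) ? log_expit(lb(i)) : log_expit(-lb(i));
        return lp;
      };
      auto log_prop = [&](const arma::vec& b) {
        arma::vec d = b - mode;
        double q = arma::as_scalar(d.t() * H * d);
        return -0.5 * (t_df + 3.0) * std::log1p(q / t_df);
      };
      double lr = log_target(prop, lin_new) - log_target(beta, lin) +
        log_prop(beta) - log_prop(prop);
      if (std::log(R::unif_rand()) < lr) {
        beta = prop;
        lin = lin_new;
      }
    }

    // ---- adaptation (burn-in only) ----------------------------------------
    if (it < n_burnin && ((it + 1) % 50 == 0)) {
      ++batch;
      double step = 1.0 / std::sqrt((double) batch);
      for (int k = 0; k < m; ++k) {
        s_scale(k) *= std::exp(step * (acc_scale(k) / 50.0 - 0.44));
        acc_scale(k) = 0;
        s_loc(k) *= std::exp(step * (acc_loc(k) / 50.0 - 0.44));
        acc_loc(k) = 0;
      }
      if (family != 0) {
        if (try_eta > 0) {
          s_eta *= std::exp(step * ((double) acc_eta / try_eta - 0.23));
          acc_eta = 0; try_eta = 0;
        }
        for (int j = 0; j < p; ++j) {
          s_lam(j)  *= std::exp(step * (acc_lam(j)  / 50.0 - 0.44));
          s_tau1(j) *= std::exp(step * (acc_tau1(j) / 50.0 - 0.44));
          s_tau2(j) *= std::exp(step * (acc_tau2(j) / 50.0 - 0.44));
          acc_lam(j) = acc_tau1(j) = acc_tau2(j) = 0;
        }
      }
    }

    // ---- record -----------------------------------------------------------
    if (it >= n_burnin) {
      const int row = it - n_burnin;
      int c0 = 0;
      for (int j = 0; j < p; ++j) draws(row, c0++) = tau1(j);
      for (int a = 0; a < nfree; ++a) draws(row, c0++) = lam(free_idx(a));
      for (int cc = 0; cc < m; ++cc)
        for (int rr = cc; rr < m; ++rr) draws(row, c0++) = Phi(rr, cc);
      if (has_sigma) for (int j = 0; j < p; ++j) draws(row, c0++) = s2_1(j);
      if (mixture) {
        for (int j = 0; j < p; ++j) draws(row, c0++) = tau2(j);
        if (has_sigma) for (int j = 0; j < p; ++j) draws(row, c0++) = s2_2(j);
        for (int r = 0; r < 3; ++r) draws(row, c0++) = beta(r);

        // posterior bot probability, Bayes' rule per draw
        if (family == 0) {
          // eta-marginalized class-1 density: MVN(tau1, Lam Phi Lam' + D1)
          arma::mat Lam(p, m, arma::fill::zeros);
          for (int j = 0; j < p; ++j) Lam(j, fac(j)) = lam(j);
          arma::mat Sig = Lam * Phi * Lam.t() + arma::diagmat(s2_1);
          arma::mat Rl = arma::chol(Sig, "lower");
          double ldet = 2.0 * arma::sum(arma::log(Rl.diag()));
          arma::mat Rc = Y.t();
          Rc.each_col() -= tau1;
          arma::mat Z = arma::solve(arma::trimatl(Rl), Rc);
          arma::rowvec d2 = arma::sum(Z % Z, 0);
          double c2const = 0.0;
          for (int j = 0; j < p; ++j) c2const += std::log(2.0 * M_PI * s2_2(j));
          for (int i = 0; i < N; ++i) {
            double l1 = -0.5 * (p * std::log(2.0 * M_PI) + ldet + d2(i)) +
              log_expit(lin(i));
            arma::rowvec yi = Y.row(i);
            double q = 0.0;
            for (int j = 0; j < p; ++j) {
              double r = yi(j) - tau2(j);
              q += r * r / s2_2(j);
            }
            double l2 = -0.5 * (c2const + q) + log_expit(-lin(i));
            pbot_sum(i) += 1.0 / (1.0 + std::exp(l1 - l2));
          }
        } else {
          for (int i = 0; i < N; ++i) {
            double l1 = loglik1_person(i, eta.row(i)) + log_expit(lin(i));
            double l2 = loglik2_person(i) + log_expit(-lin(i));
            pbot_sum(i) += 1.0 / (1.0 + std::exp(l1 - l2));
          }
        }
      }
    }
  }

  return List::create(
    _["draws"] = draws,
    _["p_bot"] = pbot_sum / (double) n_keep
  );
}
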