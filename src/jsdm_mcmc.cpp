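// Metropolis-within-Gibbs sampler for the latent-factor multispecies
// occupancy model:
//   u_ij    = beta0_i + beta1_i*TREE_j + l_j . theta_i + eps_ij
//   eps_ij ~ N(0, sigma_i^2),  sigma_i^2 = 1 - sum_t theta_it^2
//   z_ij    = 1{u_ij > 0}
//   y_ij   ~ Binomial(k_j, z_ij * p_ij),  logit p_ij = x_j . gamma_i
// with community-level normal random effects on beta and gamma.
//
// Update scheme: collapsed Bernoulli update for z (u integrated out),
// truncated-normal draw for u given z, conjugate normal updates for beta
// and the site factor scores l, adaptive random-walk Metropolis for gamma,
// theta (with rejection of rows leaving the unit ball, lower-triangular
// constraint and positive diagonal for identifiability) and the community
// SDs (on the log scale). Uses R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SS_MAX = 1.0 - 1e-6; // keep sigma^2 strictly positive

// standard normal conditioned on x > a: naive rejection while the
// acceptance rate is decent, Robert's (1995) shifted-exponential rejection
// in the tail — exact in both regimes, no quantile evaluations
static double rtnorm_std_lower(double a) {
  if (a <= 0.4) {
    for (;;) { double x = R::norm_rand(); if (x > a) return x; }
  }
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(R::unif_rand()) / alpha;
    double d = x - alpha;
    if (std::log(R::unif_rand()) <= -0.5 * d * d) return x;
  }
}

// N(m, s^2) truncated to (0, inf) if pos, else (-inf, 0]
static double rtnorm_sign(double m, double s, bool pos) {
  if (pos) return m + s * rtnorm_std_lower(-m / s);
  return m - s * rtnorm_std_lower(m / s);
}

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// binomial log-lik for one species over its occupied sites
static double gamma_loglik(const arma::rowvec& g, const arma::mat& Xd,
                           const arma::ivec& yrow, const arma::vec& k,
                           const arma::ivec& zrow) {
  double ll = 0.0;
  for (arma::uword j = 0; j < k.n_elem; ++j) {
    if (zrow(j) == 0) continue;
    double eta = g(0) * Xd(j, 0) + g(1) * Xd(j, 1) + g(2) * Xd(j, 2);
    double p = inv_logit(eta);
    p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    ll += yrow(j) * std::log(p) + (k(j) - yrow(j)) * std::log1p(-p);
  }
  return ll;
}

// [[Rcpp::export(name = ".jsdm_mcmc")]]
List jsdm_mcmc(const arma::imat& y, const arma::vec& k,
               const arma::vec& tree, const arma::vec& trailw,
               const arma::vec& vegd, int T, int n_burn, int n_iter,
               int thin, double mu_prior_var, double sd_prior_scale,
               double theta_prior_sd, bool store_latent) {
  const int n = y.n_rows, S = y.n_cols;
  const int n_keep = n_iter / thin + (n_iter % thin ? 1 : 0);

  arma::mat Xo(S, 2), Xd(S, 3);
  Xo.col(0).ones(); Xo.col(1) = tree;
  Xd.col(0).ones(); Xd.col(1) = trailw; Xd.col(2) = vegd;
  const arma::mat XtX = Xo.t() * Xo;

  // ---- state ----
  arma::mat beta(n, 2, arma::fill::zeros);
  arma::mat gam(n, 3, arma::fill::zeros);
  arma::mat theta(n, T, arma::fill::zeros);
  arma::mat l(S, T, arma::fill::zeros);
  arma::mat u(n, S, arma::fill::zeros);
  arma::imat z(n, S, arma::fill::ones);
  arma::vec mu_b(2, arma::fill::zeros), sig_b(2, arma::fill::ones);
  arma::vec mu_g(3, arma::fill::zeros), sig_g(3, arma::fill::ones);

  // dispersed initial values (consumes the chain's RNG substream)
  for (int i = 0; i < n; ++i) {
    double ybar = 0.0;
    for (int j = 0; j < S; ++j) ybar += (double)y(i, j) / k(j);
    ybar = std::min(std::max(ybar / S, 0.02), 0.8);
    gam(i, 0) = std::log(ybar / (1 - ybar)) + R::rnorm(0.0, 0.5);
    beta(i, 0) = R::rnorm(0.0, 0.5);
    beta(i, 1) = R::rnorm(0.0, 0.3);
    for (int t = 0; t < std::min(i + 1, T); ++t)
      theta(i, t) = R::rnorm(0.0, 0.1);
    if (i < T) theta(i, i) = std::fabs(theta(i, i)) + 0.05;
    double ss = arma::dot(theta.row(i), theta.row(i));
    if (ss > SS_MAX) theta.row(i) *= std::sqrt(0.5 / ss);
  }

  arma::vec step_theta(n, arma::fill::value(0.1));
  arma::vec step_gam(n, arma::fill::value(0.2));
  double step_sig = 0.25;
  arma::vec acc_theta(n, arma::fill::zeros), acc_gam(n, arma::fill::zeros);

  // ---- storage ----
  arma::cube S_beta(n_keep, n, 2), S_gam(n_keep, n, 3), S_theta(n_keep, n, T);
  arma::mat S_sig2(n_keep, n);
  arma::icube S_z;
  arma::cube S_l;
  if (store_latent) { S_z.set_size(n_keep, n, S); S_l.set_size(n_keep, S, T); }
  int kept = 0;

  arma::vec sigma2(n), sigma(n);
  for (int i = 0; i < n; ++i) {
    sigma2(i) = 1.0 - arma::dot(theta.row(i), theta.row(i));
    sigma(i) = std::sqrt(sigma2(i));
  }

  const int n_total = n_burn + n_iter;
  for (int it = 0; it < n_total; ++it) {
    // occupancy-layer mean M = beta0 + beta1*tree + theta l'
    arma::mat M = beta.col(0) * arma::rowvec(S, arma::fill::ones) +
                  beta.col(1) * tree.t() + theta * l.t();

    // detection probabilities
    arma::mat Eta = gam * Xd.t(); // n x S
    // -- z | rest (u collapsed out); forced to 1 where y > 0 --
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < S; ++j) {
        if (y(i, j) > 0) { z(i, j) = 1; continue; }
        double phi1 = R::pnorm(M(i, j) / sigma(i), 0.0, 1.0, 1, 0);
        double p = inv_logit(Eta(i, j));
        double w1 = phi1 * std::exp(k(j) * std::log1p(-std::min(p, 1.0 - 1e-12)));
        double w0 = 1.0 - phi1;
        double pr = w1 / (w1 + w0);
        z(i, j) = (R::unif_rand() < pr) ? 1 : 0;
      }
    }

    // -- u | z: truncated normal --
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < S; ++j)
        u(i, j) = rtnorm_sign(M(i, j), sigma(i), z(i, j) == 1);

    // -- beta_i | rest: conjugate bivariate normal --
    for (int i = 0; i < n; ++i) {
      arma::vec ut = u.row(i).t() - l * theta.row(i).t();
      arma::mat Prec = XtX / sigma2(i);
      Prec(0, 0) += 1.0 / (sig_b(0) * sig_b(0));
      Prec(1, 1) += 1.0 / (sig_b(1) * sig_b(1));
      arma::vec b = Xo.t() * ut / sigma2(i);
      b(0) += mu_b(0) / (sig_b(0) * sig_b(0));
      b(1) += mu_b(1) / (sig_b(1) * sig_b(1));
      arma::mat U = arma::chol(Prec); // upper: Prec = U'U
      arma::vec zr(2); zr(0) = R::norm_rand(); zr(1) = R::norm_rand();
      arma::vec mean = arma::solve(arma::trimatu(U),
                                   arma::solve(arma::trimatl(U.t()), b));
      beta.row(i) = (mean + arma::solve(arma::trimatu(U), zr)).t();
    }

    // -- l_j | rest: conjugate (shared precision across sites) --
    {
      arma::mat Dinv = arma::diagmat(1.0 / sigma2);
      arma::mat A = arma::eye(T, T) + theta.t() * Dinv * theta;
      arma::mat Resid = u - beta.col(0) * arma::rowvec(S, arma::fill::ones) -
                        beta.col(1) * tree.t(); // n x S
      arma::mat Mean = arma::solve(A, theta.t() * Dinv * Resid); // T x S
      arma::mat B = arma::inv_sympd(A);
      arma::mat Lc = arma::chol(B, "lower");
      arma::mat Zr(T, S);
      for (int t = 0; t < T; ++t)
        for (int j = 0; j < S; ++j) Zr(t, j) = R::norm_rand();
      l = (Mean + Lc * Zr).t();
    }

    // -- theta_i | rest: RW-MH on the free (lower-triangular) elements --
    for (int i = 0; i < n; ++i) {
      int nfree = std::min(i + 1, T);
      arma::vec resid = u.row(i).t() - Xo * beta.row(i).t(); // S
      arma::rowvec cur = theta.row(i);
      arma::rowvec prop = cur;
      for (int t = 0; t < nfree; ++t)
        prop(t) = cur(t) + step_theta(i) * R::norm_rand();
      double ssp = arma::dot(prop, prop);
      bool ok = ssp <= SS_MAX && !(i < T && prop(i) <= 0.0);
      if (ok) {
        double s2c = sigma2(i), s2p = 1.0 - ssp;
        arma::vec mc = l * cur.t(), mp = l * prop.t();
        double llc = 0.0, llp = 0.0;
        for (int j = 0; j < S; ++j) {
          double dc = resid(j) - mc(j), dp = resid(j) - mp(j);
          llc += -0.5 * std::log(s2c) - dc * dc / (2.0 * s2c);
          llp += -0.5 * std::log(s2p) - dp * dp / (2.0 * s2p);
        }
        for (int t = 0; t < nfree; ++t) {
          llc -= cur(t) * cur(t) / (2.0 * theta_prior_sd * theta_prior_sd);
          llp -= prop(t) * prop(t) / (2.0 * theta_prior_sd * theta_prior_sd);
        }
        if (std::log(R::unif_rand()) < llp - llc) {
          theta.row(i) = prop;
          sigma2(i) = s2p; sigma(i) = std::sqrt(s2p);
          acc_theta(i) += 1.0;
        }
      }
    }

    // -- gamma_i | rest: RW-MH --
    for (int i = 0; i < n; ++i) {
      arma::rowvec cur = gam.row(i);
      arma::rowvec prop = cur;
      for (int t = 0; t < 3; ++t) prop(t) = cur(t) + step_gam(i) * R::norm_rand();
      arma::ivec yrow = y.row(i).t(), zrow = z.row(i).t();
      double llc = gamma_loglik(cur, Xd, yrow, k, zrow);
      double llp = gamma_loglik(prop, Xd, yrow, k, zrow);
      for (int t = 0; t < 3; ++t) {
        double v = sig_g(t) * sig_g(t);
        llc -= (cur(t) - mu_g(t)) * (cur(t) - mu_g(t)) / (2.0 * v);
        llp -= (prop(t) - mu_g(t)) * (prop(t) - mu_g(t)) / (2.0 * v);
      }
      if (std::log(R::unif_rand()) < llp - llc) {
        gam.row(i) = prop;
        acc_gam(i) += 1.0;
      }
    }

    // -- community hyperparameters (beta and gamma families) --
    for (int fam = 0; fam < 5; ++fam) {
      arma::vec vals = (fam < 2) ? beta.col(fam) : gam.col(fam - 2);
      double* mu = (fam < 2) ? &mu_b(fam) : &mu_g(fam - 2);
      double* sg = (fam < 2) ? &sig_b(fam) : &sig_g(fam - 2);
      double s2 = (*sg) * (*sg);
      double prec = n / s2 + 1.0 / mu_prior_var;
      double mean = (arma::accu(vals) / s2) / prec;
      *mu = mean + R::norm_rand() / std::sqrt(prec);
      // half-normal prior on the SD; RW on log sigma with Jacobian
      double lsc = std::log(*sg);
      double lsp = lsc + step_sig * R::norm_rand();
      double sc = *sg, sp = std::exp(lsp);
      double ssq = arma::accu(arma::square(vals - *mu));
      double hs2 = sd_prior_scale * sd_prior_scale;
      double llc = -n * std::log(sc) - ssq / (2.0 * sc * sc) -
                   sc * sc / (2.0 * hs2) + std::log(sc);
      double llp = -n * std::log(sp) - ssq / (2.0 * sp * sp) -
                   sp * sp / (2.0 * hs2) + std::log(sp);
      if (std::log(R::unif_rand()) < llp - llc) *sg = sp;
    }

    // -- burn-in step-size adaptation (frozen afterwards) --
    if (it < n_burn && (it + 1) % 50 == 0) {
      for (int i = 0; i < n; ++i) {
        double ra = acc_theta(i) / 50.0;
        step_theta(i) *= std::exp(std::min(std::max(ra - 0.25, -0.5), 0.5));
        step_theta(i) = std::min(std::max(step_theta(i), 1e-3), 2.0);
        double rg = acc_gam(i) / 50.0;
        step_gam(i) *= std::exp(std::min(std::max(rg - 0.25, -0.5), 0.5));
        step_gam(i) = std::min(std::max(step_gam(i), 1e-3), 2.0);
      }
      acc_theta.zeros(); acc_gam.zeros();
    }

    // -- store --
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int i = 0; i < n; ++i) {
        S_beta(kept, i, 0) = beta(i, 0); S_beta(kept, i, 1) = beta(i, 1);
        for (int t = 0; t < 3; ++t) S_gam(kept, i, t) = gam(i, t);
        for (int t = 0; t < T; ++t) S_theta(kept, i, t) = theta(i, t);
        S_sig2(kept, i) = sigma2(i);
        if (store_latent)
          for (int j = 0; j < S; ++j) S_z(kept, i, j) = z(i, j);
      }
      if (store_latent)
        for (int j = 0; j < S; ++j)
          for (int t = 0; t < T; ++t) S_l(kept, j, t) = l(j, t);
      ++kept;
    }
  }

  List out = List::create(
    Named("beta") = S_beta, Named("gamma") = S_gam,
    Named("theta") = S_theta, Named("sigma2") = S_sig2,
    Named("n_kept") = kept);
  if (store_latent) { out["z"] = S_z; out["l"] = S_l; }
  return out;
}
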