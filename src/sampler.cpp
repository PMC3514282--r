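// Polya-Gamma augmented Gibbs sampler for the joint success/discontinuation
// logistic model. All randomness goes through R's RNG so that set.seed() on
// the R side makes every chain reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

const double TRUNC = 0.64; // truncation point of the two-piece proposal

// n-th coefficient of the alternating series for the Jacobi J*(1,0) density
double acoef(int n, double x) {
  double h = n + 0.5;
  if (x > TRUNC)
    return M_PI * h * std::exp(-0.5 * h * h * M_PI * M_PI * x);
  return M_PI * h * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * h * h / x);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC]
double rtigauss(double z) {
  const double t = TRUNC;
  double x;
  if (z < 1.0 / t) {
    // mean above the truncation point: propose from the z = 0 kernel
    // (x = t/(1 + t*E)^2 with E a constrained exponential), thin by the tilt
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (std::log(R::unif_rand()) <= -0.5 * z * z * x) return x;
    }
  }
  // mean inside (0, t]: Michael-Schucany-Haas, repeat until inside
  double mu = 1.0 / z;
  do {
    double y = R::norm_rand();
    y *= y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  } while (x > t);
  return x;
}

// one PG(1, z) draw via Devroye's alternating-series rejection sampler
double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  const double t = TRUNC;
  double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
  // log masses of the exponential tail (x > t) and IG head (x <= t) envelopes
  double logp = std::log(0.5 * M_PI / K) - K * t;
  double sqt = std::sqrt(t);
  double c1 = R::pnorm((t * z - 1.0) / sqt, 0.0, 1.0, 1, 1);
  double c2 = 2.0 * z + R::pnorm(-(t * z + 1.0) / sqt, 0.0, 1.0, 1, 1);
  double mx = (c1 > c2) ? c1 : c2;
  double logq = M_LN2 - z + mx + std::log(std::exp(c1 - mx) + std::exp(c2 - mx));
  double p_exp = 1.0 / (1.0 + std::exp(logq - logp));
  while (true) {
    double x = (R::unif_rand() < p_exp) ? t + R::exp_rand() / K : rtigauss(z);
    // squeeze the target between alternating partial sums
    double s = acoef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= acoef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += acoef(n, x);
        if (y > s) break;
      }
    }
  }
}

double rpg(int b, double z) {
  double s = 0.0;
  for (int i = 0; i < b; ++i) s += rpg1(z);
  return s;
}

arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// draw from N(A^{-1} b, A^{-1}) given precision A and linear term b
arma::vec rmvnorm_prec(const arma::mat& A, const arma::vec& b) {
  arma::mat U = arma::chol(A); // A = U' U
  arma::vec mu = arma::solve(arma::trimatu(U), arma::solve(arma::trimatl(U.t()), b));
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(A.n_rows));
}

// log conditional for a scale parameter sigma given its n latent values
// (sum of squares ss), under a half-normal(hnsd) prior, on the log-sigma scale
double lpost_logsigma(double lsig, int n, double ss, double hnsd) {
  double sig = std::exp(lsig);
  return -n * lsig - 0.5 * ss / (sig * sig) - 0.5 * sig * sig / (hnsd * hnsd) + lsig;
}

// N(m, sd) truncated to (0, inf) by inverse-CDF
double rtnorm_pos(double m, double sd) {
  double lo = R::pnorm(-m / sd, 0.0, 1.0, 1, 0);
  double u = lo + R::unif_rand() * (1.0 - lo);
  if (u >= 1.0) u = 1.0 - 1e-12;
  if (u <= 0.0) u = 1e-12;
  return m + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".rpg_cpp")]]
Rcpp::NumericVector rpg_cpp(Rcpp::IntegerVector b, Rcpp::NumericVector z) {
  int n = b.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg(b[i], z[i]);
  return out;
}

// One MCMC chain for the joint model. Couples enter through sufficient
// counts: m attempts / k live births for the success equation, r observed
// continuation decisions / s discontinuations for the dropout equation
// (probabilities are constant across a couple's attempts, so each couple is
// a pair of binomials given its latents).
// [[Rcpp::export(name = ".gibbs_joint_cpp")]]
Rcpp::List gibbs_joint_cpp(const arma::mat& Xs, const arma::mat& Xd,
                           const arma::ivec& m, const arma::ivec& k,
                           const arma::ivec& r, const arma::ivec& s,
                           const arma::vec& is_mid,
                           int est_lam_p, int est_lam_m,
                           double lam_p_fix, double lam_m_fix,
                           int est_sig_f, double sig_f_fix,
                           int est_sig_e, double sig_e_fix,
                           double tau, double hn_f, double hn_e,
                           int n_iter, int burn, int thin,
                           const arma::vec& beta_s_init,
                           const arma::vec& beta_d_init,
                           double lam_p_init, double lam_m_init,
                           double sig_f_init, double sig_e_init,
                           bool save_latent) {
  const int n = Xs.n_rows;
  const int ps = Xs.n_cols;
  const int pd = Xd.n_cols;
  const int q = est_lam_p + est_lam_m;
  const arma::vec is_par = 1.0 - is_mid;

  arma::vec kappa1(n), kappa2(n);
  for (int i = 0; i < n; ++i) {
    kappa1(i) = k(i) - 0.5 * m(i);
    kappa2(i) = s(i) - 0.5 * r(i);
  }

  arma::vec beta_s = beta_s_init;
  arma::vec beta_d = beta_d_init;
  double lam_p = est_lam_p ? lam_p_init : lam_p_fix;
  double lam_m = est_lam_m ? lam_m_init : lam_m_fix;
  double sig_f = est_sig_f ? sig_f_init : sig_f_fix;
  double sig_e = est_sig_e ? sig_e_init : sig_e_fix;
  arma::vec f(n, arma::fill::zeros), eps(n, arma::fill::zeros);
  arma::vec w1(n, arma::fill::zeros), w2(n, arma::fill::zeros);

  const bool use_f = est_sig_f || sig_f_fix > 0.0;
  const bool use_e = est_sig_e || sig_e_fix > 0.0;

  double step_f = 0.3, step_e = 0.3;
  int acc_f = 0, acc_e = 0, try_f = 0, try_e = 0;

  const int n_keep = (n_iter - burn) / thin;
  const int npar = ps + pd + 4;
  arma::mat out(n_keep, npar);
  arma::mat flat;
  if (save_latent) flat.set_size(n_keep, n);

  arma::mat Z(n, pd + q);
  Z.cols(0, pd - 1) = Xd;

  int keep = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // --- Polya-Gamma draws ---
    arma::vec cs = Xs * beta_s;
    arma::vec cd = Xd * beta_d;
    arma::vec lamv = lam_p * is_par + lam_m * is_mid;
    for (int i = 0; i < n; ++i) {
      w1(i) = rpg(m(i), cs(i) + f(i));
      double zeta = cd(i) + lamv(i) * f(i) + eps(i);
      w2(i) = r(i) > 0 ? rpg(r(i), zeta) : 0.0;
    }

    // --- success-equation coefficients ---
    {
      arma::mat A = Xs.t() * (Xs.each_col() % w1);
      A.diag() += 1.0 / (tau * tau);
      arma::vec b = Xs.t() * (kappa1 - w1 % f);
      beta_s = rmvnorm_prec(A, b);
      cs = Xs * beta_s;
    }

    // --- discontinuation-equation coefficients and free loadings ---
    {
      int col = pd;
      if (est_lam_p) Z.col(col++) = f % is_par;
      if (est_lam_m) Z.col(col++) = f % is_mid;
      arma::mat Zq = Z.cols(0, pd + q - 1);
      arma::vec off = eps;
      if (!est_lam_p && lam_p_fix != 0.0) off += lam_p_fix * (f % is_par);
      if (!est_lam_m && lam_m_fix != 0.0) off += lam_m_fix * (f % is_mid);
      arma::mat A = Zq.t() * (Zq.each_col() % w2);
      A.diag() += 1.0 / (tau * tau);
      arma::vec b = Zq.t() * (kappa2 - w2 % off);
      arma::vec draw = rmvnorm_prec(A, b);
      beta_d = draw.head(pd);
      int col2 = pd;
      if (est_lam_p) lam_p = draw(col2++);
      if (est_lam_m) lam_m = draw(col2++);
      cd = Xd * beta_d;
      lamv = lam_p * is_par + lam_m * is_mid;
    }

    // --- shared latent factor ---
    if (use_f && sig_f > 0.0) {
      for (int i = 0; i < n; ++i) {
        double prec = 1.0 / (sig_f * sig_f) + w1(i) + lamv(i) * lamv(i) * w2(i);
        double lin = (kappa1(i) - w1(i) * cs(i)) +
                     lamv(i) * (kappa2(i) - w2(i) * (cd(i) + eps(i)));
        f(i) = lin / prec + R::norm_rand() / std::sqrt(prec);
      }
    }

    // --- couple-level dropout disturbance ---
    if (use_e && sig_e > 0.0) {
      for (int i = 0; i < n; ++i) {
        double prec = 1.0 / (sig_e * sig_e) + w2(i);
        double lin = kappa2(i) - w2(i) * (cd(i) + lamv(i) * f(i));
        eps(i) = lin / prec + R::norm_rand() / std::sqrt(prec);
      }
    }

    // --- scale parameters: adaptive random-walk MH on the log scale ---
    if (est_sig_f) {
      ++try_f;
      double lsig = std::log(sig_f);
      double prop = lsig + step_f * R::norm_rand();
      double ss = arma::dot(f, f);
      double lr = lpost_logsigma(prop, n, ss, hn_f) - lpost_logsigma(lsig, n, ss, hn_f);
      bool ok = std::log(R::unif_rand()) < lr;
      if (ok) { sig_f = std::exp(prop); ++acc_f; }
      if (it <= burn) step_f *= std::exp(((ok ? 1.0 : 0.0) - 0.44) / std::sqrt((double)it));
    }
    if (est_sig_e) {
      ++try_e;
      double lsig = std::log(sig_e);
      double prop = lsig + step_e * R::norm_rand();
      double ss = arma::dot(eps, eps);
      double lr = lpost_logsigma(prop, n, ss, hn_e) - lpost_logsigma(lsig, n, ss, hn_e);
      bool ok = std::log(R::unif_rand()) < lr;
      if (ok) { sig_e = std::exp(prop); ++acc_e; }
      if (it <= burn) step_e *= std::exp(((ok ? 1.0 : 0.0) - 0.44) / std::sqrt((double)it));
    }

    // --- interweaving (ASIS): re-draw each scale in the non-centered
    // parameterization, where it enters the linear predictors with
    // coefficient u_i = f_i/sigma (resp. v_i = eps_i/sigma) and is
    // conditionally a positive truncated normal; then rescale the latents.
    // Dramatically improves mixing of weakly informed scales.
    if (est_sig_f && sig_f > 0.0) {
      double prec = 1.0 / (hn_f * hn_f), lin = 0.0;
      for (int i = 0; i < n; ++i) {
        double u = f(i) / sig_f;
        double lu = lamv(i) * u;
        prec += w1(i) * u * u + w2(i) * lu * lu;
        lin += u * (kappa1(i) - w1(i) * cs(i)) +
               lu * (kappa2(i) - w2(i) * (cd(i) + eps(i)));
      }
      double newsig = rtnorm_pos(lin / prec, 1.0 / std::sqrt(prec));
      f *= newsig / sig_f;
      sig_f = newsig;
    }
    if (est_sig_e && sig_e > 0.0) {
      double prec = 1.0 / (hn_e * hn_e), lin = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = eps(i) / sig_e;
        prec += w2(i) * v * v;
        lin += v * (kappa2(i) - w2(i) * (cd(i) + lamv(i) * f(i)));
      }
      double newsig = rtnorm_pos(lin / prec, 1.0 / std::sqrt(prec));
      eps *= newsig / sig_e;
      sig_e = newsig;
    }

    if (it > burn && (it - burn) % thin == 0 && keep < n_keep) {
      int c = 0;
      for (int j = 0; j < ps; ++j) out(keep, c++) = beta_s(j);
      for (int j = 0; j < pd; ++j) out(keep, c++) = beta_d(j);
      out(keep, c++) = lam_p;
      out(keep, c++) = lam_m;
      out(keep, c++) = sig_f;
      out(keep, c++) = sig_e;
      if (save_latent) flat.row(keep) = f.t();
      ++keep;
    }
  }

  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("draws") = out,
      Rcpp::Named("accept_sigma_f") = try_f > 0 ? (double)acc_f / try_f : NA_REAL,
      Rcpp::Named("accept_sigma_eps") = try_e > 0 ? (double)acc_e / try_e : NA_REAL);
  if (save_latent) res["latent_f"] = flat;
  return res;
}
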