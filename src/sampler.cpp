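// Gibbs-within-Metropolis-Hastings sampler for Bayesian spatial-temporal
// AFT models with intrinsic CAR / MCAR frailty priors.
//
// Candidate models (q = frailty block dimension per unit):
//   M1: lp = mu + x'beta + omega_i                         (q = 1)
//   M2: lp = mu + x'beta + xi*z + gamma_i*z + omega_i      (q = 2, z = j-1)
//   M3: lp = mu + x'beta + xi_j + gamma_ij + omega_i       (q = 1+J, xi_1 = 0)
//
// Update order per iteration: beta (componentwise MH), xi (MH), mu (MH),
// frailty blocks Delta_i component-by-component (MH against the unit's
// likelihood terms plus the MCAR conditional), log sigma (MH with
// inverse-gamma prior on sigma^2), Lambda (exact Wishart draw), then
// per-component sum-to-zero centering absorbed into mu / xi.
//
// All randomness comes from R's RNG so set.seed() governs the chain.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;

// log-density / log-survival of the standardised residual
static inline double res_log_f(double e, int family) {
  switch (family) {
    case 1: return e - std::exp(e);                       // extreme value
    case 2: return -e - 2.0 * std::log1p(std::exp(-e));   // logistic
    default: return -0.5 * e * e - LOG_SQRT_2PI;          // normal
  }
}
static inline double res_log_S(double e, int family) {
  switch (family) {
    case 1: return -std::exp(e);
    case 2: return -std::log1p(std::exp(e));
    default: return R::pnorm(e, 0.0, 1.0, 0, 1);
  }
}

struct LikContext {
  const arma::vec* logY;
  const arma::ivec* delta;
  double log_sigma;
  double sigma;
  int family;
  double clamp;
  bool prior_only;
};

// likelihood contribution of one record at linear predictor lp
static inline double rec_ll(const LikContext& ctx, int n, double lp) {
  double e = ((*ctx.logY)(n) - lp) / ctx.sigma;
  if (e > ctx.clamp) e = ctx.clamp;
  if (e < -ctx.clamp) e = -ctx.clamp;
  if ((*ctx.delta)(n) == 1)
    return -ctx.log_sigma - (*ctx.logY)(n) + res_log_f(e, ctx.family);
  return res_log_S(e, ctx.family);
}

static double subset_ll(const LikContext& ctx, const std::vector<int>& idx,
                        const arma::vec& lp) {
  if (ctx.prior_only) return 0.0;
  double s = 0.0;
  for (int n : idx) s += rec_ll(ctx, n, lp(n));
  return s;
}

static double full_ll(const LikContext& ctx, const arma::vec& lp) {
  if (ctx.prior_only) return 0.0;
  double s = 0.0;
  for (arma::uword n = 0; n < lp.n_elem; ++n) s += rec_ll(ctx, n, lp(n));
  return s;
}

// Wishart(df, S) draw via Bartlett decomposition, using R's RNG
static arma::mat rwishart(double df, const arma::mat& S) {
  int q = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

struct Block {
  double s;          // step size
  int win_acc = 0, win_try = 0;   // adaptation window
  long acc = 0, tries = 0;        // post-burn-in totals
  explicit Block(double s0 = 0.1) : s(s0) {}
  void count(bool accepted, bool burnin) {
    if (burnin) { win_try++; if (accepted) win_acc++; }
    else { tries++; if (accepted) acc++; }
  }
  void adapt(double target) {
    if (win_try == 0) return;
    double rate = double(win_acc) / win_try;
    if (rate > target) s *= 1.1; else s /= 1.1;
    win_acc = 0; win_try = 0;
  }
};

// [[Rcpp::export]]
List chain_run_cpp(const arma::vec& logY, const arma::ivec& delta,
                   const arma::mat& X, const arma::ivec& unit,
                   const arma::ivec& cohort, int I, int J,
                   int model, int family, const arma::imat& C,
                   int n_burnin, int n_keep, int thin,
                   double clamp, double wishart_df, const arma::mat& wishart_R,
                   double sig_a, double sig_b,
                   double s_init, double adapt_target, int adapt_window,
                   bool fix_sigma, double sigma_init,
                   bool prior_only, bool fix_lambda,
                   const arma::mat& Lambda_init, bool include_frailty) {
  const int n = logY.n_elem;
  const int p = X.n_cols;
  const int q = (model == 1) ? 1 : (model == 2 ? 2 : 1 + J);
  const int n_xi = (model == 1) ? 0 : (model == 2 ? 1 : J - 1);

  // record index lists
  std::vector<std::vector<int>> by_unit(I);
  std::vector<std::vector<int>> by_unit_cohort;
  if (model == 3) by_unit_cohort.resize((size_t)I * J);
  for (int r = 0; r < n; ++r) {
    by_unit[unit(r)].push_back(r);
    if (model == 3) by_unit_cohort[(size_t)unit(r) * J + cohort(r)].push_back(r);
  }
  // neighbour lists
  std::vector<std::vector<int>> nbr(I);
  for (int i = 0; i < I; ++i)
    for (int k = 0; k < I; ++k)
      if (C(i, k) == 1) nbr[i].push_back(k);

  // state
  double mu = 0.0;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec xi(std::max(n_xi, 1), arma::fill::zeros); // padded; use first n_xi
  arma::mat Delta(I, q, arma::fill::zeros);
  double sigma = sigma_init;
  arma::mat Lambda = Lambda_init;

  LikContext ctx{&logY, &delta, std::log(sigma), sigma, family, clamp,
                 prior_only};

  // step-size blocks: mu, beta[p], xi[n_xi], delta-component[q], sigma
  Block b_mu(s_init), b_sigma(s_init);
  std::vector<Block> b_beta(p, Block(s_init));
  std::vector<Block> b_xi(n_xi, Block(s_init));
  std::vector<Block> b_delta(q, Block(s_init));

  arma::vec lp(n);
  std::vector<int> all_idx(n);
  for (int r = 0; r < n; ++r) all_idx[r] = r;
  arma::vec zd(n);                 // cohort as continuous covariate z = j
  for (int r = 0; r < n; ++r) zd(r) = (double)cohort(r);
  std::vector<std::vector<int>> by_cohort;   // M3: records of cohort k (>=1)
  if (model == 3) {
    by_cohort.resize(J);
    for (int r = 0; r < n; ++r) by_cohort[cohort(r)].push_back(r);
  }

  auto recompute_lp = [&]() {
    lp = mu + X * beta;
    for (int r = 0; r < n; ++r) {
      int i = unit(r), j = cohort(r);
      double z = (double)j;
      if (model == 1) {
        lp(r) += Delta(i, 0);
      } else if (model == 2) {
        lp(r) += xi(0) * z + Delta(i, 1) * z + Delta(i, 0);
      } else {
        double xij = (j >= 1) ? xi(j - 1) : 0.0;
        lp(r) += xij + Delta(i, 1 + j) + Delta(i, 0);
      }
    }
  };

  // generic scalar MH on a likelihood subset with additive lp perturbation
  // lp(idx) -> lp(idx) + d * mult[idx] (mult == nullptr means mult = 1);
  // prior_at supplies the log-prior as a function of the scalar.
  auto mh_shift = [&](const std::vector<int>& idx, const double* mult,
                      double cur, Block& blk, bool burnin,
                      const std::function<double(double)>& prior_at) -> double {
    double w = norm_rand();
    double u = unif_rand();
    double d = blk.s * w;
    double newv = cur + d;
    double dll = 0.0;
    if (!ctx.prior_only) {
      if (mult) {
        for (int nn : idx) {
          double m = mult[nn];
          if (m == 0.0) continue;
          dll += rec_ll(ctx, nn, lp(nn) + d * m) - rec_ll(ctx, nn, lp(nn));
        }
      } else {
        for (int nn : idx)
          dll += rec_ll(ctx, nn, lp(nn) + d) - rec_ll(ctx, nn, lp(nn));
      }
    }
    double dprior = prior_at(newv) - prior_at(cur);
    double dtot = dll + dprior;
    bool accept = R_finite(dtot) && (dtot > std::log(u));
    blk.count(accept, burnin);
    if (accept) {
      if (mult) { for (int nn : idx) lp(nn) += d * mult[nn]; }
      else { for (int nn : idx) lp(nn) += d; }
      return newv;
    }
    return cur;
  };

  const std::function<double(double)> flat = [](double) { return 0.0; };

  int n_iter = n_burnin + n_keep;
  int n_out = n_keep / thin;
  int n_par = 1 + p + n_xi + (include_frailty ? I * q : 0) + 1 +
              (include_frailty && !fix_lambda ? q * (q + 1) / 2 : 0);
  arma::mat draws(n_out, n_par);
  arma::vec deviance(n_out);
  int out_row = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool burnin = it < n_burnin;
    recompute_lp();

    if (!prior_only) {
      // Step 1: beta, componentwise
      for (int k = 0; k < p; ++k) {
        beta(k) = mh_shift(all_idx, X.colptr(k), beta(k), b_beta[k],
                           burnin, flat);
      }
      // Step 2: xi
      for (int k = 0; k < n_xi; ++k) {
        if (model == 2) {
          xi(0) = mh_shift(all_idx, zd.memptr(), xi(0), b_xi[0], burnin, flat);
        } else { // M3: xi_k shifts only cohort k+1's records
          xi(k) = mh_shift(by_cohort[k + 1], nullptr, xi(k), b_xi[k],
                           burnin, flat);
        }
      }
      // intercept
      mu = mh_shift(all_idx, nullptr, mu, b_mu, burnin, flat);
    }

    // Step 3: frailty blocks
    if (include_frailty) {
      for (int i = 0; i < I; ++i) {
        int ni = (int)nbr[i].size();
        arma::vec mbar(q, arma::fill::zeros);
        double prec_mult = 1.0; // island: marginal N(0, Lambda^{-1})
        if (ni > 0) {
          for (int k : nbr[i]) mbar += Delta.row(k).t();
          mbar /= ni;
          prec_mult = (double)ni;
        }
        for (int c = 0; c < q; ++c) {
          // MCAR conditional as a function of Delta(i, c)
          auto prior_at = [&](double v) {
            arma::vec d = Delta.row(i).t() - mbar;
            d(c) = v - mbar(c);
            return -0.5 * prec_mult * arma::as_scalar(d.t() * Lambda * d);
          };
          const std::vector<int>& idx =
            (model == 3 && c >= 1) ? by_unit_cohort[(size_t)i * J + (c - 1)]
                                   : by_unit[i];
          const double* mult = (model == 2 && c == 1) ? zd.memptr() : nullptr;
          Delta(i, c) = mh_shift(idx, mult, Delta(i, c), b_delta[c], burnin,
                                 prior_at);
        }
      }
    }

    // Step 4: sigma via MH on log sigma (inverse-gamma(sig_a, sig_b) on
    // sigma^2; Jacobians for the log-sigma parameterisation included)
    if (!fix_sigma && !prior_only) {
      double theta = std::log(sigma);
      double w = norm_rand(), u = unif_rand();
      double theta_new = theta + b_sigma.s * w;
      double cur_ll = full_ll(ctx, lp);
      LikContext ctx_new = ctx;
      ctx_new.sigma = std::exp(theta_new);
      ctx_new.log_sigma = theta_new;
      double new_ll = full_ll(ctx_new, lp);
      auto lprior = [&](double th) { return -2.0 * sig_a * th -
                                            sig_b * std::exp(-2.0 * th); };
      double dtot = (new_ll - cur_ll) + (lprior(theta_new) - lprior(theta));
      bool accept = R_finite(dtot) && (dtot > std::log(u));
      b_sigma.count(accept, burnin);
      if (accept) {
        sigma = std::exp(theta_new);
        ctx.sigma = sigma;
        ctx.log_sigma = theta_new;
      }
    }

    // Step 5: Lambda ~ Wishart(p_w + I, (R^{-1} + V)^{-1})
    if (include_frailty && !fix_lambda) {
      arma::mat V(q, q, arma::fill::zeros);
      for (int i = 0; i < I; ++i)
        for (int k : nbr[i])
          if (k > i) {
            arma::vec d = Delta.row(i).t() - Delta.row(k).t();
            V += d * d.t();
          }
      arma::mat S = arma::inv_sympd(arma::inv_sympd(wishart_R) + V);
      Lambda = rwishart(wishart_df + I, S);
    }

    // identifiability: per-component sum-to-zero centering, absorbed into
    // mu / xi so every linear predictor is unchanged
    if (include_frailty) {
      arma::rowvec cm = arma::mean(Delta, 0);
      Delta.each_row() -= cm;
      if (model == 1) {
        mu += cm(0);
      } else if (model == 2) {
        mu += cm(0);
        xi(0) += cm(1);
      } else {
        mu += cm(0) + cm(1);                    // omega mean + ref-cohort mean
        for (int k = 0; k < n_xi; ++k) xi(k) += cm(1 + k + 1) - cm(1);
      }
    }

    // burn-in step-size adaptation
    if (burnin && ((it + 1) % adapt_window == 0)) {
      b_mu.adapt(adapt_target);
      b_sigma.adapt(adapt_target);
      for (auto& b : b_beta) b.adapt(adapt_target);
      for (auto& b : b_xi) b.adapt(adapt_target);
      for (auto& b : b_delta) b.adapt(adapt_target);
    }

    // record
    if (!burnin && ((it - n_burnin) % thin == 0)) {
      recompute_lp();
      int col = 0;
      draws(out_row, col++) = mu;
      for (int k = 0; k < p; ++k) draws(out_row, col++) = beta(k);
      for (int k = 0; k < n_xi; ++k) draws(out_row, col++) = xi(k);
      if (include_frailty)
        for (int c = 0; c < q; ++c)
          for (int i = 0; i < I; ++i) draws(out_row, col++) = Delta(i, c);
      draws(out_row, col++) = sigma;
      if (include_frailty && !fix_lambda)
        for (int c = 0; c < q; ++c)
          for (int d2 = 0; d2 <= c; ++d2) draws(out_row, col++) = Lambda(d2, c);
      deviance(out_row) = -2.0 * full_ll(ctx, lp);
      out_row++;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  auto rate = [](const Block& b) {
    return b.tries > 0 ? double(b.acc) / b.tries : NA_REAL;
  };
  std::vector<std::string> blk_names;
  std::vector<double> blk_rates, blk_steps;
  blk_names.push_back("mu"); blk_rates.push_back(rate(b_mu));
  blk_steps.push_back(b_mu.s);
  for (int k = 0; k < p; ++k) {
    blk_names.push_back("beta." + std::to_string(k + 1));
    blk_rates.push_back(rate(b_beta[k])); blk_steps.push_back(b_beta[k].s);
  }
  for (int k = 0; k < n_xi; ++k) {
    blk_names.push_back("xi." + std::to_string(k + 1));
    blk_rates.push_back(rate(b_xi[k])); blk_steps.push_back(b_xi[k].s);
  }
  if (include_frailty)
    for (int c = 0; c < q; ++c) {
      blk_names.push_back("delta." + std::to_string(c + 1));
      blk_rates.push_back(rate(b_delta[c])); blk_steps.push_back(b_delta[c].s);
    }
  if (!fix_sigma && !prior_only) {
    blk_names.push_back("sigma");
    blk_rates.push_back(rate(b_sigma)); blk_steps.push_back(b_sigma.s);
  }

  return List::create(
    _["draws"] = draws,
    _["deviance"] = deviance,
    _["block"] = blk_names,
    _["acceptance"] = blk_rates,
    _["step_size"] = blk_steps,
    _["q"] = q, _["n_xi"] = n_xi);
}

// Full-data conditional log-likelihood (same kernel as the sampler); used
// for deviance-at-posterior-mean and cross-checks against the R evaluator.
// [[Rcpp::export]]
double loglik_cpp(const arma::vec& logY, const arma::ivec& delta,
                  const arma::mat& X, const arma::ivec& unit,
                  const arma::ivec& cohort, int model, int family,
                  double mu, const arma::vec& beta, const arma::vec& xi,
                  const arma::mat& Delta, double sigma, double clamp) {
  int n = logY.n_elem;
  LikContext ctx{&logY, &delta, std::log(sigma), sigma, family, clamp, false};
  double s = 0.0;
  for (int r = 0; r < n; ++r) {
    int i = unit(r), j = cohort(r);
    double z = (double)j;
    double l = mu + arma::dot(X.row(r), beta);
    if (model == 1) l += Delta(i, 0);
    else if (model == 2) l += xi(0) * z + Delta(i, 1) * z + Delta(i, 0);
    else {
      if (j >= 1) l += xi(j - 1);
      l += Delta(i, 1 + j) + Delta(i, 0);
    }
    s += rec_ll(ctx, r, l);
  }
  return s;
}
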