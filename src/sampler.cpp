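// Random-walk Metropolis-Hastings samplers over (beta, tau2, I) for the
// one-component model and (beta1, beta2, tau2_1, tau2_2, I1, I2) for the
// two-component model. The R level owns validation, initialization, proposal
// tuning and diagnostics; these routines only run the chains.
//
// RNG contract (single R RNG stream, fixed consumption order per iteration):
//   1. beta proposal rnorm, 2. beta accept runif,
//   3. [full Bayes] log-precision proposal rnorm, 4. its accept runif,
//      (two-component: slope/precision blocks for component 1 then 2)
//   5. [indicator move] SNP pick runif, 6. state pick (two-component) runif,
//   7. accept runif -- not consumed when the move is auto-rejected by the
//      minimum-instrument rule.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// single-SNP likelihood contribution (0 when excluded)
static inline double term1(double beta, double tau2, double g, double G,
                           double sx2, double sy2, bool full_var) {
  double vf = beta * beta * sx2 + sy2 + tau2;
  double vl = full_var ? vf : sy2 + tau2;
  double r = G - beta * g;
  return -0.5 * LOG2PI - 0.5 * (std::log(vl) + r * r / vf);
}

static double loglik_one(double beta, double tau2, const std::vector<int>& I,
                         const NumericVector& g, const NumericVector& G,
                         const NumericVector& sx2, const NumericVector& sy2,
                         bool full_var) {
  double s = 0.0;
  for (int j = 0; j < (int)I.size(); ++j)
    if (I[j]) s += term1(beta, tau2, g[j], G[j], sx2[j], sy2[j], full_var);
  return s;
}

// DerSimonian-Laird tau2 on the included set (first-order weights);
// returns 0 when fewer than 2 SNPs are included.
static double dl_tau2_set(const std::vector<int>& I, const NumericVector& g,
                          const NumericVector& G, const NumericVector& sy2) {
  int k = 0;
  double sw = 0.0, swr = 0.0, sw2 = 0.0;
  for (int j = 0; j < (int)I.size(); ++j) {
    if (!I[j]) continue;
    double w = g[j] * g[j] / sy2[j];
    double r = G[j] / g[j];
    sw += w; swr += w * r; sw2 += w * w; ++k;
  }
  if (k < 2) return 0.0;
  double bbar = swr / sw;
  double Q = 0.0;
  for (int j = 0; j < (int)I.size(); ++j) {
    if (!I[j]) continue;
    double w = g[j] * g[j] / sy2[j];
    double r = G[j] / g[j];
    Q += w * (r - bbar) * (r - bbar);
  }
  double denom = sw - sw2 / sw;
  double t = (Q - (k - 1)) / denom;
  return t > 0.0 ? t : 0.0;
}

static inline double lprior_beta(double beta, double beta_sd) {
  return R::dnorm(beta, 0.0, beta_sd, 1);
}
static inline double lprior_prec(double tau2, double shape, double rate) {
  return R::dgamma(1.0 / tau2, shape, 1.0 / rate, 1);
}

// [[Rcpp::export]]
double cpp_log_posterior_one(double beta, double tau2, IntegerVector I,
                             NumericVector gamma_hat, NumericVector Gamma_hat,
                             NumericVector se_x, NumericVector se_y,
                             double eta, bool full_bayes, bool full_var,
                             double beta_sd, double prec_shape, double prec_rate,
                             NumericVector log_p, NumericVector log_1mp) {
  int L = gamma_hat.size();
  NumericVector sx2 = se_x * se_x, sy2 = se_y * se_y;
  std::vector<int> Iv(I.begin(), I.end());
  int k = 0;
  for (int j = 0; j < L; ++j) k += Iv[j];
  double lp = loglik_one(beta, tau2, Iv, gamma_hat, Gamma_hat, sx2, sy2, full_var)
    + 0.5 * eta * k + lprior_beta(beta, beta_sd);
  if (full_bayes) lp += lprior_prec(tau2, prec_shape, prec_rate);
  for (int j = 0; j < L; ++j) lp += Iv[j] ? log_p[j] : log_1mp[j];
  return lp;
}

// [[Rcpp::export]]
List cpp_mh_one(NumericVector gamma_hat, NumericVector Gamma_hat,
                NumericVector se_x, NumericVector se_y,
                int iterations, int burn_in, bool dl_mode, bool full_var,
                double eta, int min_instruments,
                double beta_sd, double prec_shape, double prec_rate,
                NumericVector log_p, NumericVector log_1mp,
                double prop_sd_beta, double prop_sd_logprec,
                double beta_init, double tau2_init, IntegerVector I_init,
                bool update_indicators, bool use_likelihood) {
  int L = gamma_hat.size();
  NumericVector sx2 = se_x * se_x, sy2 = se_y * se_y;
  std::vector<int> I(I_init.begin(), I_init.end());
  int k = 0;
  for (int j = 0; j < L; ++j) k += I[j];

  double beta = beta_init, tau2 = tau2_init;
  double ll = use_likelihood ?
    loglik_one(beta, tau2, I, gamma_hat, Gamma_hat, sx2, sy2, full_var) : 0.0;

  int n_keep = iterations - burn_in;
  NumericVector beta_draws(n_keep), tau2_draws(n_keep), lp_draws(n_keep);
  IntegerMatrix I_draws(n_keep, L);
  int acc_beta = 0, acc_prec = 0, acc_flip = 0, prop_flip = 0, auto_rej = 0;

  for (int it = 0; it < iterations; ++it) {
    // (a) slope update
    double beta_p = beta + R::rnorm(0.0, prop_sd_beta);
    double ll_p = use_likelihood ?
      loglik_one(beta_p, tau2, I, gamma_hat, Gamma_hat, sx2, sy2, full_var) : 0.0;
    double la = (ll_p - ll) + lprior_beta(beta_p, beta_sd) - lprior_beta(beta, beta_sd);
    double u = R::runif(0.0, 1.0);
    if (std::log(u) < la) { beta = beta_p; ll = ll_p; ++acc_beta; }

    // (b) pleiotropy variance update
    if (dl_mode) {
      tau2 = dl_tau2_set(I, gamma_hat, Gamma_hat, sy2);
      ll = use_likelihood ?
        loglik_one(beta, tau2, I, gamma_hat, Gamma_hat, sx2, sy2, full_var) : 0.0;
    } else {
      double lprec = -std::log(tau2);
      double lprec_p = lprec + R::rnorm(0.0, prop_sd_logprec);
      double tau2_p = std::exp(-lprec_p);
      double llv = use_likelihood ?
        loglik_one(beta, tau2_p, I, gamma_hat, Gamma_hat, sx2, sy2, full_var) : 0.0;
      double lb = (llv - ll)
        + lprior_prec(tau2_p, prec_shape, prec_rate)
        - lprior_prec(tau2, prec_shape, prec_rate)
        + (lprec_p - lprec); // Jacobian of the log-precision walk
      double u2 = R::runif(0.0, 1.0);
      if (std::log(u2) < lb) { tau2 = tau2_p; ll = llv; ++acc_prec; }
    }

    // (c) single-indicator flip
    if (update_indicators) {
      int j = (int)std::floor(R::runif(0.0, 1.0) * L);
      if (j >= L) j = L - 1;
      int new_k = I[j] ? k - 1 : k + 1;
      ++prop_flip;
      if (new_k < min_instruments) {
        ++auto_rej; // rejected without consuming an accept draw
      } else {
        double tj = term1(beta, tau2, gamma_hat[j], Gamma_hat[j], sx2[j], sy2[j],
                          full_var);
        double sgn = I[j] ? -1.0 : 1.0;
        double lc = use_likelihood ? sgn * (tj + 0.5 * eta) : 0.0;
        lc += sgn * (log_p[j] - log_1mp[j]);
        double u3 = R::runif(0.0, 1.0);
        if (std::log(u3) < lc) {
          I[j] = 1 - I[j];
          k = new_k;
          if (use_likelihood) ll += sgn * tj;
          ++acc_flip;
        }
      }
    }

    if (it >= burn_in) {
      int idx = it - burn_in;
      beta_draws[idx] = beta;
      tau2_draws[idx] = tau2;
      for (int j = 0; j < L; ++j) I_draws(idx, j) = I[j];
      double lp = ll + 0.5 * eta * k + lprior_beta(beta, beta_sd);
      if (!dl_mode) lp += lprior_prec(tau2, prec_shape, prec_rate);
      for (int j = 0; j < L; ++j) lp += I[j] ? log_p[j] : log_1mp[j];
      lp_draws[idx] = lp;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["tau2"] = tau2_draws, _["indicators"] = I_draws,
    _["log_post"] = lp_draws,
    _["accept"] = List::create(
      _["beta"] = (double)acc_beta / iterations,
      _["prec"] = dl_mode ? NA_REAL : (double)acc_prec / iterations,
      _["flip"] = prop_flip > 0 ? (double)acc_flip / prop_flip : NA_REAL,
      _["flip_auto_reject"] = prop_flip > 0 ? (double)auto_rej / prop_flip : NA_REAL));
}

static double loglik_two(double b1, double t1, double b2, double t2,
                         const std::vector<int>& S, const NumericVector& g,
                         const NumericVector& G, const NumericVector& sx2,
                         const NumericVector& sy2, bool full_var) {
  double s = 0.0;
  for (int j = 0; j < (int)S.size(); ++j) {
    if (S[j] == 1) s += term1(b1, t1, g[j], G[j], sx2[j], sy2[j], full_var);
    else if (S[j] == 2) s += term1(b2, t2, g[j], G[j], sx2[j], sy2[j], full_var);
  }
  return s;
}

static double dl_component(const std::vector<int>& S, int comp,
                           const NumericVector& g, const NumericVector& G,
                           const NumericVector& sy2) {
  std::vector<int> I(S.size(), 0);
  for (size_t j = 0; j < S.size(); ++j) I[j] = (S[j] == comp) ? 1 : 0;
  return dl_tau2_set(I, g, G, sy2);
}

// [[Rcpp::export]]
double cpp_log_posterior_two(double beta1, double tau2_1, double beta2,
                             double tau2_2, IntegerVector state,
                             NumericVector gamma_hat, NumericVector Gamma_hat,
                             NumericVector se_x, NumericVector se_y,
                             double eta1, double eta2, bool full_bayes,
                             bool full_var, double beta_sd,
                             double prec_shape, double prec_rate,
                             NumericVector log_p1, NumericVector log_1mp1,
                             NumericVector log_p2, NumericVector log_1mp2) {
  int L = gamma_hat.size();
  NumericVector sx2 = se_x * se_x, sy2 = se_y * se_y;
  std::vector<int> S(state.begin(), state.end());
  int n1 = 0, n2 = 0;
  for (int j = 0; j < L; ++j) { n1 += S[j] == 1; n2 += S[j] == 2; }
  double lp = loglik_two(beta1, tau2_1, beta2, tau2_2, S, gamma_hat, Gamma_hat,
                         sx2, sy2, full_var)
    + 0.5 * eta1 * n1 + 0.5 * eta2 * n2
    + lprior_beta(beta1, beta_sd) + lprior_beta(beta2, beta_sd);
  if (full_bayes) lp += lprior_prec(tau2_1, prec_shape, prec_rate)
    + lprior_prec(tau2_2, prec_shape, prec_rate);
  for (int j = 0; j < L; ++j) {
    lp += (S[j] == 1) ? log_p1[j] : log_1mp1[j];
    lp += (S[j] == 2) ? log_p2[j] : log_1mp2[j];
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_mh_two(NumericVector gamma_hat, NumericVector Gamma_hat,
                NumericVector se_x, NumericVector se_y,
                int iterations, int burn_in, bool dl_mode, bool full_var,
                double eta1, double eta2, int min_instruments,
                double beta_sd, double prec_shape, double prec_rate,
                NumericVector log_p1, NumericVector log_1mp1,
                NumericVector log_p2, NumericVector log_1mp2,
                double prop_sd_beta, double prop_sd_logprec,
                double beta1_init, double beta2_init,
                double tau2_1_init, double tau2_2_init, IntegerVector S_init,
                bool update_indicators, bool use_likelihood) {
  int L = gamma_hat.size();
  NumericVector sx2 = se_x * se_x, sy2 = se_y * se_y;
  std::vector<int> S(S_init.begin(), S_init.end());
  int n1 = 0, n2 = 0;
  for (int j = 0; j < L; ++j) { n1 += S[j] == 1; n2 += S[j] == 2; }

  double b1 = beta1_init, b2 = beta2_init;
  double t1 = tau2_1_init, t2 = tau2_2_init;
  double ll = use_likelihood ?
    loglik_two(b1, t1, b2, t2, S, gamma_hat, Gamma_hat, sx2, sy2, full_var) : 0.0;

  int n_keep = iterations - burn_in;
  NumericVector b1_draws(n_keep), b2_draws(n_keep), t1_draws(n_keep),
    t2_draws(n_keep), lp_draws(n_keep);
  IntegerMatrix S_draws(n_keep, L);
  int acc_b1 = 0, acc_b2 = 0, acc_p1 = 0, acc_p2 = 0,
    acc_move = 0, prop_move = 0, auto_rej = 0;

  for (int it = 0; it < iterations; ++it) {
    // slope blocks
    for (int comp = 1; comp <= 2; ++comp) {
      double cur = comp == 1 ? b1 : b2;
      double prop = cur + R::rnorm(0.0, prop_sd_beta);
      double ll_p = use_likelihood ?
        (comp == 1
           ? loglik_two(prop, t1, b2, t2, S, gamma_hat, Gamma_hat, sx2, sy2, full_var)
           : loglik_two(b1, t1, prop, t2, S, gamma_hat, Gamma_hat, sx2, sy2, full_var))
        : 0.0;
      double la = (ll_p - ll) + lprior_beta(prop, beta_sd) - lprior_beta(cur, beta_sd);
      double u = R::runif(0.0, 1.0);
      if (std::log(u) < la) {
        if (comp == 1) { b1 = prop; ++acc_b1; } else { b2 = prop; ++acc_b2; }
        ll = ll_p;
      }
    }

    // pleiotropy variance blocks
    if (dl_mode) {
      t1 = dl_component(S, 1, gamma_hat, Gamma_hat, sy2);
      t2 = dl_component(S, 2, gamma_hat, Gamma_hat, sy2);
      ll = use_likelihood ?
        loglik_two(b1, t1, b2, t2, S, gamma_hat, Gamma_hat, sx2, sy2, full_var) : 0.0;
    } else {
      for (int comp = 1; comp <= 2; ++comp) {
        double cur = comp == 1 ? t1 : t2;
        double lprec = -std::log(cur);
        double lprec_p = lprec + R::rnorm(0.0, prop_sd_logprec);
        double tau2_p = std::exp(-lprec_p);
        double ll_p = use_likelihood ?
          (comp == 1
             ? loglik_two(b1, tau2_p, b2, t2, S, gamma_hat, Gamma_hat, sx2, sy2, full_var)
             : loglik_two(b1, t1, b2, tau2_p, S, gamma_hat, Gamma_hat, sx2, sy2, full_var))
          : 0.0;
        double lb = (ll_p - ll)
          + lprior_prec(tau2_p, prec_shape, prec_rate)
          - lprior_prec(cur, prec_shape, prec_rate)
          + (lprec_p - lprec);
        double u = R::runif(0.0, 1.0);
        if (std::log(u) < lb) {
          if (comp == 1) { t1 = tau2_p; ++acc_p1; } else { t2 = tau2_p; ++acc_p2; }
          ll = ll_p;
        }
      }
    }

    // indicator move: one SNP, uniformly random different state in {S0,S1,S2}
    if (update_indicators) {
      int j = (int)std::floor(R::runif(0.0, 1.0) * L);
      if (j >= L) j = L - 1;
      int cur = S[j];
      int others[2], m = 0;
      for (int s = 0; s <= 2; ++s) if (s != cur) others[m++] = s;
      int prop = others[R::runif(0.0, 1.0) < 0.5 ? 0 : 1];
      ++prop_move;
      int n_inc = n1 + n2 + ((prop != 0) - (cur != 0));
      if (n_inc < min_instruments) {
        ++auto_rej;
      } else {
        double old_term = 0.0, new_term = 0.0, dpen = 0.0, dprior = 0.0;
        if (cur == 1) {
          old_term = term1(b1, t1, gamma_hat[j], Gamma_hat[j], sx2[j], sy2[j], full_var);
          dpen -= 0.5 * eta1; dprior += log_1mp1[j] - log_p1[j];
        } else if (cur == 2) {
          old_term = term1(b2, t2, gamma_hat[j], Gamma_hat[j], sx2[j], sy2[j], full_var);
          dpen -= 0.5 * eta2; dprior += log_1mp2[j] - log_p2[j];
        }
        if (prop == 1) {
          new_term = term1(b1, t1, gamma_hat[j], Gamma_hat[j], sx2[j], sy2[j], full_var);
          dpen += 0.5 * eta1; dprior += log_p1[j] - log_1mp1[j];
        } else if (prop == 2) {
          new_term = term1(b2, t2, gamma_hat[j], Gamma_hat[j], sx2[j], sy2[j], full_var);
          dpen += 0.5 * eta2; dprior += log_p2[j] - log_1mp2[j];
        }
        double lc = (use_likelihood ? (new_term - old_term + dpen) : 0.0) + dprior;
        double u = R::runif(0.0, 1.0);
        if (std::log(u) < lc) {
          if (use_likelihood) ll += new_term - old_term;
          n1 += (prop == 1) - (cur == 1);
          n2 += (prop == 2) - (cur == 2);
          S[j] = prop;
          ++acc_move;
        }
      }
    }

    if (it >= burn_in) {
      int idx = it - burn_in;
      b1_draws[idx] = b1; b2_draws[idx] = b2;
      t1_draws[idx] = t1; t2_draws[idx] = t2;
      for (int j = 0; j < L; ++j) S_draws(idx, j) = S[j];
      double lp = ll + 0.5 * eta1 * n1 + 0.5 * eta2 * n2
        + lprior_beta(b1, beta_sd) + lprior_beta(b2, beta_sd);
      if (!dl_mode) lp += lprior_prec(t1, prec_shape, prec_rate)
        + lprior_prec(t2, prec_shape, prec_rate);
      for (int j = 0; j < L; ++j) {
        lp += (S[j] == 1) ? log_p1[j] : log_1mp1[j];
        lp += (S[j] == 2) ? log_p2[j] : log_1mp2[j];
      }
      lp_draws[idx] = lp;
    }
  }

  return List::create(
    _["beta1"] = b1_draws, _["beta2"] = b2_draws,
    _["tau2_1"] = t1_draws, _["tau2_2"] = t2_draws,
    _["state"] = S_draws, _["log_post"] = lp_draws,
    _["accept"] = List::create(
      _["beta1"] = (double)acc_b1 / iterations,
      _["beta2"] = (double)acc_b2 / iterations,
      _["prec1"] = dl_mode ? NA_REAL : (double)acc_p1 / iterations,
      _["prec2"] = dl_mode ? NA_REAL : (double)acc_p2 / iterations,
      _["move"] = prop_move > 0 ? (double)acc_move / prop_move : NA_REAL,
      _["move_auto_reject"] = prop_move > 0 ? (double)auto_rej / prop_move : NA_REAL));
}
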