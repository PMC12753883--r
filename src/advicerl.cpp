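#include <Rcpp.h>
using namespace Rcpp;

// Packed parameter-index layout (0-based slots into the parameter vector):
// idx[0] alpha_c for positive PE, idx[1] alpha_c for negative PE,
// idx[2] tau_c, idx[3] tau_a, then n_cond slots of advice alpha (positive
// PE), n_cond of advice alpha (negative PE), n_cond of omega. Symmetric
// models point the positive and negative slots at the same parameter.
// Frame codes: 0 mixed (+1/-1, init 0, counterfactual -R), 1 gain (+1/0,
// init 0.5, cf 1-R), 2 loss (0/-1, init -0.5, cf -1-R).

static inline double counterfactual(int frame, double R) {
  if (frame == 1) return 1.0 - R;
  if (frame == 2) return -1.0 - R;
  return -R;
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// One full session replay; returns total loglik, optionally filling
// per-trial contributions.
static double session_ll(const int* choice_green, const int* advice_green,
                         const int* advice_correct, const int* phr,
                         const double* rew, int n, const double* par,
                         const int* idx, int n_cond, int fict_self,
                         int fict_adv, int frame, int literal, double v_init,
                         double* out_trials) {
  const double ac_pos = par[idx[0]], ac_neg = par[idx[1]];
  const double tau_c = par[idx[2]], tau_a = par[idx[3]];
  const int* aa_pos = idx + 4;
  const int* aa_neg = idx + 4 + n_cond;
  const int* i_om = idx + 4 + 2 * n_cond;
  double vg = v_init, vb = v_init, vf = 0.0, vu = 0.0;
  double total = 0.0;
  for (int t = 0; t < n; ++t) {
    double pc = logistic(tau_c * (vg - vb));
    double pa = logistic(tau_a * (vf - vu));
    double om = par[i_om[phr[t]]];
    double p;
    if (literal) {
      double beta = advice_green[t] ? 1.0 : -1.0;
      p = beta * om * pa + (1.0 - om) * pc;
      if (p < 1e-6) p = 1e-6;
      if (p > 1.0 - 1e-6) p = 1.0 - 1e-6;
    } else {
      double a = advice_green[t] ? pa : 1.0 - pa;
      p = om * a + (1.0 - om) * pc;
    }
    double p_obs = choice_green[t] ? p : 1.0 - p;
    if (p_obs < 1e-12) p_obs = 1e-12;
    double ll = std::log(p_obs);
    if (out_trials) out_trials[t] = ll;
    total += ll;
    // self update (chosen card; counterfactual on unchosen if fictitious)
    double R = rew[t];
    if (choice_green[t]) {
      double pe = R - vg;
      vg += (pe > 0 ? ac_pos : ac_neg) * pe;
      if (fict_self) {
        double pe2 = counterfactual(frame, R) - vb;
        vb += (pe2 > 0 ? ac_pos : ac_neg) * pe2;
      }
    } else {
      double pe = R - vb;
      vb += (pe > 0 ? ac_pos : ac_neg) * pe;
      if (fict_self) {
        double pe2 = counterfactual(frame, R) - vg;
        vg += (pe2 > 0 ? ac_pos : ac_neg) * pe2;
      }
    }
    // advice update (always observed from feedback)
    double Ra = advice_correct[t] ? 1.0 : -1.0;
    double pe = Ra - vf;
    vf += par[(pe > 0 ? aa_pos : aa_neg)[phr[t]]] * pe;
    if (fict_adv) {
      double pe2 = -Ra - vu;
      vu += par[(pe2 > 0 ? aa_pos : aa_neg)[phr[t]]] * pe2;
    }
  }
  return total;
}

struct SessDat {
  std::vector<int> choice_green, advice_green, advice_correct, phr;
  std::vector<double> rew;
  int n;
};

static std::vector<SessDat> unpack_sessions(List subj_mats, List subj_rews) {
  int ns = subj_mats.size();
  std::vector<SessDat> out(ns);
  for (int j = 0; j < ns; ++j) {
    IntegerMatrix m = subj_mats[j];
    NumericVector r = subj_rews[j];
    int n = m.nrow();
    out[j].n = n;
    out[j].choice_green.resize(n); out[j].advice_green.resize(n);
    out[j].advice_correct.resize(n); out[j].phr.resize(n);
    out[j].rew.resize(n);
    for (int t = 0; t < n; ++t) {
      out[j].choice_green[t] = m(t, 0);
      out[j].advice_green[t] = m(t, 1);
      out[j].advice_correct[t] = m(t, 2);
      out[j].phr[t] = m(t, 3);
      out[j].rew[t] = r[t];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_session_loglik(IntegerMatrix dat, NumericVector rew,
                                 NumericVector par, IntegerVector idx,
                                 int fict_self, int fict_adv, int frame,
                                 int literal, double v_init) {
  int n = dat.nrow();
  int n_cond = (idx.size() - 4) / 3;
  std::vector<int> cg(n), ag(n), ac(n), ph(n);
  for (int t = 0; t < n; ++t) {
    cg[t] = dat(t, 0); ag[t] = dat(t, 1); ac[t] = dat(t, 2); ph[t] = dat(t, 3);
  }
  NumericVector out(n);
  session_ll(cg.data(), ag.data(), ac.data(), ph.data(),
             REAL(rew), n, REAL(par), INTEGER(idx), n_cond, fict_self,
             fict_adv, frame, literal, v_init, REAL(out));
  return out;
}

// Draws x observations matrix of per-trial log-likelihoods: theta has one
// row per draw holding the concatenated individual parameter vectors
// (subject-major), n_ip parameters per subject.
// [[Rcpp::export]]
NumericMatrix cpp_loglik_matrix(List subj_mats, List subj_rews,
                                NumericMatrix theta, int n_ip,
                                IntegerVector idx, int fict_self,
                                int fict_adv, int frame, int literal,
                                double v_init) {
  std::vector<SessDat> dat = unpack_sessions(subj_mats, subj_rews);
  int ns = dat.size();
  int n_cond = (idx.size() - 4) / 3;
  int n_obs = 0;
  for (int j = 0; j < ns; ++j) n_obs += dat[j].n;
  int S = theta.nrow();
  NumericMatrix out(S, n_obs);
  std::vector<double> buf;
  std::vector<double> pv(n_ip);
  for (int s = 0; s < S; ++s) {
    int off = 0;
    for (int j = 0; j < ns; ++j) {
      buf.resize(dat[j].n);
      // theta is column-major; gather this draw's subject block
      for (int k = 0; k < n_ip; ++k) pv[k] = theta(s, j * n_ip + k);
      session_ll(dat[j].choice_green.data(), dat[j].advice_green.data(),
                 dat[j].advice_correct.data(), dat[j].phr.data(),
                 dat[j].rew.data(), dat[j].n, pv.data(), INTEGER(idx),
                 n_cond, fict_self, fict_adv, frame, literal, v_init,
                 buf.data());
      for (int t = 0; t < dat[j].n; ++t) out(s, off + t) = buf[t];
      off += dat[j].n;
    }
  }
  return out;
}

// Simulate choices for every subject on its recorded environment under one
// parameter draw per replicate; returns n_rep x n_trials matrix of the
// across-subject mean green-choice rate. Environments must share n_trials.
// env matrices columns: correct_green, advice_green, advice_correct, phr.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_rates(List env_mats, NumericMatrix theta,
                                 int n_ip, IntegerVector idx, int fict_self,
                                 int fict_adv, int frame, int literal,
                                 double v_init) {
  int ns = env_mats.size();
  int n_cond = (idx.size() - 4) / 3;
  IntegerMatrix m0 = env_mats[0];
  int n = m0.nrow();
  int S = theta.nrow();
  NumericMatrix out(S, n);
  RNGScope scope;
  const int* id = INTEGER(idx);
  for (int s = 0; s < S; ++s) {
    std::vector<double> green_count(n, 0.0);
    for (int j = 0; j < ns; ++j) {
      IntegerMatrix m = env_mats[j];
      std::vector<double> pv(n_ip);
      for (int k = 0; k < n_ip; ++k) pv[k] = theta(s, j * n_ip + k);
      const double ac_pos = pv[id[0]], ac_neg = pv[id[1]];
      const double tau_c = pv[id[2]], tau_a = pv[id[3]];
      const int* aa_pos = id + 4;
      const int* aa_neg = id + 4 + n_cond;
      const int* i_om = id + 4 + 2 * n_cond;
      double vg = v_init, vb = v_init, vf = 0.0, vu = 0.0;
      for (int t = 0; t < n; ++t) {
        int correct_green = m(t, 0), advice_green = m(t, 1);
        int advice_correct = m(t, 2), ph = m(t, 3);
        double pc = logistic(tau_c * (vg - vb));
        double pa = logistic(tau_a * (vf - vu));
        double om = pv[i_om[ph]];
        double p;
        if (literal) {
          double beta = advice_green ? 1.0 : -1.0;
          p = beta * om * pa + (1.0 - om) * pc;
          if (p < 1e-6) p = 1e-6;
          if (p > 1.0 - 1e-6) p = 1.0 - 1e-6;
        } else {
          double a = advice_green ? pa : 1.0 - pa;
          p = om * a + (1.0 - om) * pc;
        }
        int choose_green = unif_rand() < p ? 1 : 0;
        if (choose_green) green_count[t] += 1.0;
        int correct = (choose_green == correct_green) ? 1 : 0;
        double R;
        if (frame == 1) R = correct ? 1.0 : 0.0;
        else if (frame == 2) R = correct ? 0.0 : -1.0;
        else R = correct ? 1.0 : -1.0;
        if (choose_green) {
          double pe = R - vg; vg += (pe > 0 ? ac_pos : ac_neg) * pe;
          if (fict_self) {
            double pe2 = counterfactual(frame, R) - vb;
            vb += (pe2 > 0 ? ac_pos : ac_neg) * pe2;
          }
        } else {
          double pe = R - vb; vb += (pe > 0 ? ac_pos : ac_neg) * pe;
          if (fict_self) {
            double pe2 = counterfactual(frame, R) - vg;
            vg += (pe2 > 0 ? ac_pos : ac_neg) * pe2;
          }
        }
        double Ra = advice_correct ? 1.0 : -1.0;
        double pe = Ra - vf;
        vf += pv[(pe > 0 ? aa_pos : aa_neg)[ph]] * pe;
        if (fict_adv) {
          double pe2 = -Ra - vu;
          vu += pv[(pe2 > 0 ? aa_pos : aa_neg)[ph]] * pe2;
        }
      }
    }
    for (int t = 0; t < n; ++t) out(s, t) = green_count[t] / ns;
  }
  return out;
}

// ---------------- hierarchical sampler -----------------------------------

// log of the truncated-normal normalising constant on [lo, hi]
static inline double log_trunc_Z(double mu, double sig, double lo, double hi) {
  double z = R::pnorm(hi, mu, sig, 1, 0) - R::pnorm(lo, mu, sig, 1, 0);
  if (z < 1e-300) z = 1e-300;
  return std::log(z);
}

// Adaptive Metropolis-within-Gibbs for the hierarchical model:
//   group means ~ Uniform(lo, hi); group sds ~ half-Cauchy(hc_scale);
//   individual parameters ~ Normal(mu, sigma) truncated to [lo, hi];
//   Bernoulli choice likelihood from the RL model.
// Per sweep: every individual parameter, every group mean, every group sd
// (log scale), plus one translation move per parameter dimension that
// shifts the group mean together with all individual values (mixes the
// mean through the hierarchical funnel). Proposal scales adapt toward 44%
// acceptance during warmup and are frozen afterwards. One chain per call;
// all randomness from R's RNG.
// [[Rcpp::export]]
List cpp_fit_chain(List subj_mats, List subj_rews, NumericMatrix theta0,
                   NumericVector mu0, NumericVector sig0,
                   NumericVector lower, NumericVector upper,
                   NumericVector hc_scale, IntegerVector idx, int fict_self,
                   int fict_adv, int frame, int literal, double v_init,
                   int n_sweeps, int n_warmup, int thin,
                   IntegerMatrix swap_pairs) {
  std::vector<SessDat> dat = unpack_sessions(subj_mats, subj_rews);
  const int ns = dat.size();
  const int nip = mu0.size();
  const int n_cond = (idx.size() - 4) / 3;
  const int* id = INTEGER(idx);
  RNGScope scope;

  std::vector<std::vector<double>> theta(ns, std::vector<double>(nip));
  for (int j = 0; j < ns; ++j)
    for (int k = 0; k < nip; ++k) theta[j][k] = theta0(j, k);
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sig(sig0.begin(), sig0.end());

  auto ll_subj = [&](int j, const double* pv) {
    return session_ll(dat[j].choice_green.data(), dat[j].advice_green.data(),
                      dat[j].advice_correct.data(), dat[j].phr.data(),
                      dat[j].rew.data(), dat[j].n, pv, id, n_cond,
                      fict_self, fict_adv, frame, literal, v_init, nullptr);
  };
  std::vector<double> ll(ns);
  for (int j = 0; j < ns; ++j) ll[j] = ll_subj(j, theta[j].data());

  // proposal scales and acceptance counters
  std::vector<std::vector<double>> s_th(ns, std::vector<double>(nip));
  std::vector<double> s_mu(nip), s_sig(nip, 0.3), s_tr(nip);
  for (int k = 0; k < nip; ++k) {
    double r = upper[k] - lower[k];
    s_mu[k] = 0.1 * r; s_tr[k] = 0.05 * r;
    for (int j = 0; j < ns; ++j) s_th[j][k] = 0.1 * r;
  }
  std::vector<std::vector<int>> a_th(ns, std::vector<int>(nip, 0));
  std::vector<std::vector<int>> n_rw(ns, std::vector<int>(nip, 0));
  std::vector<int> a_mu(nip, 0), a_sig(nip, 0), a_tr(nip, 0), a_sc(nip, 0);
  std::vector<int> n_mu(nip, 0), n_sig(nip, 0);
  std::vector<double> s_sc(nip, 0.15);
  const int adapt_every = 25;
  const double target = 0.44;

  int n_keep = (n_sweeps - n_warmup) / thin;
  NumericMatrix draws(n_keep, 2 * nip + ns * nip);
  int kept = 0;

  std::vector<double> prop(nip);
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    // individual parameters: random walk, or an independence proposal
    // from the hierarchical prior (decorrelates weakly identified
    // parameters; the truncated-normal terms cancel exactly)
    for (int j = 0; j < ns; ++j) {
      std::copy(theta[j].begin(), theta[j].end(), prop.begin());
      for (int k = 0; k < nip; ++k) {
        double cur = theta[j][k];
        if (unif_rand() < 0.5) {
          double plo = R::pnorm(lower[k], mu[k], sig[k], 1, 0);
          double phi = R::pnorm(upper[k], mu[k], sig[k], 1, 0);
          double cand = R::qnorm(plo + unif_rand() * (phi - plo),
                                 mu[k], sig[k], 1, 0);
          if (cand > lower[k] && cand < upper[k]) {
            prop[k] = cand;
            double ll_new = ll_subj(j, prop.data());
            double lp = ll_new - ll[j];
            if (lp >= 0 || unif_rand() < std::exp(lp)) {
              theta[j][k] = cand; ll[j] = ll_new;
            } else {
              prop[k] = cur;
            }
          }
          continue;
        }
        double cand = cur + s_th[j][k] * norm_rand();
        n_rw[j][k]++;
        if (cand <= lower[k] || cand >= upper[k]) continue;
        prop[k] = cand;
        double d1 = (cur - mu[k]) / sig[k], d2 = (cand - mu[k]) / sig[k];
        double lp = -0.5 * (d2 * d2 - d1 * d1);
        double ll_new = ll_subj(j, prop.data());
        lp += ll_new - ll[j];
        if (lp >= 0 || unif_rand() < std::exp(lp)) {
          theta[j][k] = cand; ll[j] = ll_new; a_th[j][k]++;
        } else {
          prop[k] = cur;
        }
      }
    }
    // group means: random walk, or an independence draw from the uniform
    // prior (fast mixing when the group mean is weakly identified)
    for (int k = 0; k < nip; ++k) {
      bool indep = unif_rand() < 0.5;
      double cand = indep
        ? lower[k] + unif_rand() * (upper[k] - lower[k])
        : mu[k] + s_mu[k] * norm_rand();
      if (!indep) n_mu[k]++;
      if (cand <= lower[k] || cand >= upper[k]) continue;
      double lp = 0.0;
      for (int j = 0; j < ns; ++j) {
        double d1 = (theta[j][k] - mu[k]) / sig[k];
        double d2 = (theta[j][k] - cand) / sig[k];
        lp += -0.5 * (d2 * d2 - d1 * d1);
      }
      lp -= ns * (log_trunc_Z(cand, sig[k], lower[k], upper[k]) -
                  log_trunc_Z(mu[k], sig[k], lower[k], upper[k]));
      if (lp >= 0 || unif_rand() < std::exp(lp)) {
        mu[k] = cand;
        if (!indep) a_mu[k]++;
      }
    }
    // group sds: random walk on log sigma (half-Cauchy prior + Jacobian),
    // or an independence draw from the half-Cauchy prior itself (prior and
    // proposal cancel, leaving only the truncated-normal terms)
    for (int k = 0; k < nip; ++k) {
      bool indep = unif_rand() < 0.5;
      double cand;
      if (indep) {
        cand = hc_scale[k] * std::tan(M_PI_2 * unif_rand());
        if (!std::isfinite(cand) || cand <= 0) continue;
      } else {
        cand = sig[k] * std::exp(s_sig[k] * norm_rand());
        n_sig[k]++;
      }
      double lp = 0.0;
      for (int j = 0; j < ns; ++j) {
        double d = theta[j][k] - mu[k];
        lp += -0.5 * d * d * (1.0 / (cand * cand) - 1.0 / (sig[k] * sig[k]));
      }
      lp += -ns * (std::log(cand) - std::log(sig[k]));
      lp -= ns * (log_trunc_Z(mu[k], cand, lower[k], upper[k]) -
                  log_trunc_Z(mu[k], sig[k], lower[k], upper[k]));
      if (!indep) {
        double h = hc_scale[k];
        lp += std::log1p((sig[k] / h) * (sig[k] / h)) -
              std::log1p((cand / h) * (cand / h));
        lp += std::log(cand) - std::log(sig[k]); // Jacobian of log walk
      }
      if (lp >= 0 || unif_rand() < std::exp(lp)) {
        sig[k] = cand;
        if (!indep) a_sig[k]++;
      }
    }
    // translation moves: shift mu[k] and all theta[.,k] together
    for (int k = 0; k < nip; ++k) {
      double delta = s_tr[k] * norm_rand();
      double mu_new = mu[k] + delta;
      if (mu_new <= lower[k] || mu_new >= upper[k]) continue;
      bool ok = true;
      for (int j = 0; j < ns; ++j) {
        double v = theta[j][k] + delta;
        if (v <= lower[k] || v >= upper[k]) { ok = false; break; }
      }
      if (!ok) continue;
      double lp = -ns * (log_trunc_Z(mu_new, sig[k], lower[k], upper[k]) -
                         log_trunc_Z(mu[k], sig[k], lower[k], upper[k]));
      std::vector<double> ll_new(ns);
      for (int j = 0; j < ns; ++j) {
        std::copy(theta[j].begin(), theta[j].end(), prop.begin());
        prop[k] += delta;
        ll_new[j] = ll_subj(j, prop.data());
        lp += ll_new[j] - ll[j];
      }
      if (lp >= 0 || unif_rand() < std::exp(lp)) {
        mu[k] = mu_new;
        for (int j = 0; j < ns; ++j) { theta[j][k] += delta; ll[j] = ll_new[j]; }
        a_tr[k]++;
      }
    }
    // scale moves: rescale sigma[k] and all deviations theta[.,k] - mu[k]
    // together (mixes the group sd through the hierarchical funnel)
    for (int k = 0; k < nip; ++k) {
      double c = std::exp(s_sc[k] * norm_rand());
      double sig_new = sig[k] * c;
      bool ok = true;
      std::vector<double> th_new(ns);
      for (int j = 0; j < ns; ++j) {
        th_new[j] = mu[k] + c * (theta[j][k] - mu[k]);
        if (th_new[j] <= lower[k] || th_new[j] >= upper[k]) { ok = false; break; }
      }
      if (!ok) continue;
      double h = hc_scale[k];
      double lp = std::log1p((sig[k] / h) * (sig[k] / h)) -
                  std::log1p((sig_new / h) * (sig_new / h));
      lp += std::log(c);
      lp -= ns * (log_trunc_Z(mu[k], sig_new, lower[k], upper[k]) -
                  log_trunc_Z(mu[k], sig[k], lower[k], upper[k]));
      std::vector<double> ll_new(ns);
      for (int j = 0; j < ns; ++j) {
        std::copy(theta[j].begin(), theta[j].end(), prop.begin());
        prop[k] = th_new[j];
        ll_new[j] = ll_subj(j, prop.data());
        lp += ll_new[j] - ll[j];
      }
      if (lp >= 0 || unif_rand() < std::exp(lp)) {
        sig[k] = sig_new;
        for (int j = 0; j < ns; ++j) { theta[j][k] = th_new[j]; ll[j] = ll_new[j]; }
        a_sc[k]++;
      }
    }
    // per-participant exchanges: swap one subject's paired rates, keeping
    // the group levels fixed (population terms enter, truncation mass
    // cancels since it depends only on the group parameters)
    for (int pr = 0; pr < swap_pairs.ncol(); ++pr) {
      int k1 = swap_pairs(0, pr), k2 = swap_pairs(1, pr);
      for (int j = 0; j < ns; ++j) {
        std::copy(theta[j].begin(), theta[j].end(), prop.begin());
        std::swap(prop[k1], prop[k2]);
        double d1a = (theta[j][k1] - mu[k1]) / sig[k1];
        double d2a = (theta[j][k2] - mu[k2]) / sig[k2];
        double d1b = (prop[k1] - mu[k1]) / sig[k1];
        double d2b = (prop[k2] - mu[k2]) / sig[k2];
        double lp = -0.5 * (d1b * d1b + d2b * d2b - d1a * d1a - d2a * d2a);
        double ll_new = ll_subj(j, prop.data());
        lp += ll_new - ll[j];
        if (lp >= 0 || unif_rand() < std::exp(lp)) {
          std::swap(theta[j][k1], theta[j][k2]);
          ll[j] = ll_new;
        }
      }
    }
    // mode-exchange moves: asymmetric-rate posteriors have a mirrored mode
    // in which the positive- and negative-PE rates trade roles; propose
    // exchanging the two parameters' whole hierarchies (mu, sigma and all
    // individual values). The proposal is symmetric and the priors of the
    // paired parameters are identical, so only the likelihood enters.
    for (int pr = 0; pr < swap_pairs.ncol(); ++pr) {
      int k1 = swap_pairs(0, pr), k2 = swap_pairs(1, pr);
      double lp = 0.0;
      std::vector<double> ll_new(ns);
      for (int j = 0; j < ns; ++j) {
        std::copy(theta[j].begin(), theta[j].end(), prop.begin());
        std::swap(prop[k1], prop[k2]);
        ll_new[j] = ll_subj(j, prop.data());
        lp += ll_new[j] - ll[j];
      }
      if (lp >= 0 || unif_rand() < std::exp(lp)) {
        std::swap(mu[k1], mu[k2]);
        std::swap(sig[k1], sig[k2]);
        for (int j = 0; j < ns; ++j) {
          std::swap(theta[j][k1], theta[j][k2]);
          ll[j] = ll_new[j];
        }
      }
    }
    // adaptation during warmup
    if (sweep <= n_warmup && sweep % adapt_every == 0) {
      auto tune = [&](double& s, int& acc, int n_try, double lo_cap,
                      double hi_cap) {
        if (n_try > 0) {
          double rate = (double)acc / n_try;
          s *= std::exp(rate - target);
          if (s < lo_cap) s = lo_cap;
          if (s > hi_cap) s = hi_cap;
        }
        acc = 0;
      };
      for (int k = 0; k < nip; ++k) {
        double r = upper[k] - lower[k];
        for (int j = 0; j < ns; ++j) {
          tune(s_th[j][k], a_th[j][k], n_rw[j][k], 1e-4 * r, r);
          n_rw[j][k] = 0;
        }
        tune(s_mu[k], a_mu[k], n_mu[k], 1e-4 * r, r); n_mu[k] = 0;
        tune(s_sig[k], a_sig[k], n_sig[k], 1e-3, 3.0); n_sig[k] = 0;
        tune(s_tr[k], a_tr[k], adapt_every, 1e-4 * r, r);
        tune(s_sc[k], a_sc[k], adapt_every, 1e-3, 2.0);
      }
    }
    // storage
    if (sweep > n_warmup && (sweep - n_warmup) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < nip; ++k) {
        draws(kept, k) = mu[k];
        draws(kept, nip + k) = sig[k];
      }
      for (int j = 0; j < ns; ++j)
        for (int k = 0; k < nip; ++k)
          draws(kept, 2 * nip + j * nip + k) = theta[j][k];
      ++kept;
    }
    if (sweep % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws);
}
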