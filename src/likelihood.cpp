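// Shared likelihood kernel for the word-learning model family.
//
// One flat parameter vector (fixed layout, 34 entries) drives every model
// variant; the variant only changes how combined-design (exp3) rows map
// parameters to a choice probability. The same kernel is used by the MCMC
// sampler, marginal-likelihood estimation and posterior prediction, so the
// likelihood is one code path throughout the package.
//
// Layout (0-based):
//   0 alpha intercept, 1 alpha slope
//   2 rho intercept,   3 rho slope        (logit)
//   4 theta intercept, 5 theta slope      (logit)
//   6..17  theta object intercept offsets (12, standardized)
//   18..29 theta object slope offsets     (12, standardized)
//   30 log sd of intercept offsets, 31 log sd of slope offsets
//   32 phi intercept, 33 phi slope        (logit; biased variants only)
//
// The object offsets are stored non-centred: the logit-scale offset of
// object j is exp(par[30]) * par[6 + j] (intercept) and
// exp(par[31]) * par[18 + j] (slope). This removes the funnel between the
// offsets and their scale that a centred parameterization produces when the
// true offset spread is small.

#include <Rcpp.h>
using namespace Rcpp;

static const int N_PAR = 34;

inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// pragmatic listener's probability of the novel referent given the novel
// word: speaker soft-max likelihood times referent prior, normalised
inline double l1_p_novel(double alpha, double theta, double prior) {
  if (prior <= 0.0) return 0.0;
  if (prior >= 1.0) return 1.0;
  double kN = 1.0 / (1.0 + std::pow(1.0 - theta, alpha));
  double kF = 1.0 / (1.0 + std::pow(1.0 + theta, alpha));
  double num = prior * kN;
  return num / (num + (1.0 - prior) * kF);
}

struct TrialData {
  const int *y;
  const double *age;
  const int *expid;  // 1, 2, 3
  const int *cond;   // 0 none, 1 congruent, 2 incongruent
  const int *obj;    // 0-based object index, -1 if absent
  int n;
  int model;         // 1 integration .. 6 developmental_bias
  double center;
  int alpha_log_link;
};

// choice probability of row i under parameter vector par
inline double row_prob(const TrialData &d, const double *par, int i) {
  double ac = d.age[i] - d.center;
  if (d.expid[i] == 2) {
    return inv_logit(par[2] + par[3] * ac);
  }
  double lpa = par[0] + par[1] * ac;
  double alpha = d.alpha_log_link ? std::exp(lpa) : (lpa > 0.0 ? lpa : 0.0);
  int j = d.obj[i];
  double off0 = j >= 0 ? std::exp(par[30]) * par[6 + j] : 0.0;
  double off1 = j >= 0 ? std::exp(par[31]) * par[18 + j] : 0.0;
  double theta = inv_logit(par[4] + off0 + (par[5] + off1) * ac);
  if (d.expid[i] == 1) {
    return l1_p_novel(alpha, theta, 0.5);
  }
  // combined design: condition sets the common-ground prior
  double rho = inv_logit(par[2] + par[3] * ac);
  double prior = (d.cond[i] == 1) ? rho : 1.0 - rho;
  switch (d.model) {
  case 1:  // integration
    return l1_p_novel(alpha, theta, prior);
  case 2: {  // no word knowledge: pooled semantic trajectory
    double theta_pooled = inv_logit(par[4] + par[5] * ac);
    return l1_p_novel(alpha, theta_pooled, prior);
  }
  case 3:  // no common ground
    return l1_p_novel(alpha, theta, 0.5);
  case 4:  // no speaker informativeness
    return prior;
  case 5: {  // biased (constant bias)
    double phi = inv_logit(par[32]);
    return phi * l1_p_novel(alpha, theta, 0.5) + (1.0 - phi) * prior;
  }
  default: {  // developmental bias
    double phi = inv_logit(par[32] + par[33] * ac);
    return phi * l1_p_novel(alpha, theta, 0.5) + (1.0 - phi) * prior;
  }
  }
}

inline double row_loglik(const TrialData &d, const double *par, int i) {
  double p = row_prob(d, par, i);
  return d.y[i] ? std::log(p) : std::log1p(-p);
}

static TrialData make_data(const IntegerVector &y, const NumericVector &age,
                           const IntegerVector &expid, const IntegerVector &cond,
                           const IntegerVector &obj, int model, double center,
                           int alpha_log_link) {
  TrialData d;
  d.y = INTEGER(y); d.age = REAL(age); d.expid = INTEGER(expid);
  d.cond = INTEGER(cond); d.obj = INTEGER(obj);
  d.n = y.size(); d.model = model; d.center = center;
  d.alpha_log_link = alpha_log_link;
  return d;
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector par, IntegerVector y, NumericVector age,
                  IntegerVector expid, IntegerVector cond, IntegerVector obj,
                  int model, double center, int alpha_log_link) {
  TrialData d = make_data(y, age, expid, cond, obj, model, center,
                          alpha_log_link);
  double ll = 0.0;
  for (int i = 0; i < d.n; ++i) ll += row_loglik(d, REAL(par), i);
  return ll;
}

// log-likelihood of the data for each row of a draw matrix
// [[Rcpp::export]]
NumericVector cpp_loglik_matrix(NumericMatrix draws, IntegerVector y,
                                NumericVector age, IntegerVector expid,
                                IntegerVector cond, IntegerVector obj,
                                int model, double center, int alpha_log_link) {
  TrialData d = make_data(y, age, expid, cond, obj, model, center,
                          alpha_log_link);
  int m = draws.nrow();
  NumericVector out(m);
  std::vector<double> par(N_PAR);
  for (int s = 0; s < m; ++s) {
    for (int k = 0; k < N_PAR; ++k) par[k] = draws(s, k);
    double ll = 0.0;
    for (int i = 0; i < d.n; ++i) ll += row_loglik(d, par.data(), i);
    out[s] = ll;
  }
  return out;
}

// choice probabilities: rows of the data by draws of the posterior
// [[Rcpp::export]]
NumericMatrix cpp_prob_matrix(NumericMatrix draws, IntegerVector y,
                              NumericVector age, IntegerVector expid,
                              IntegerVector cond, IntegerVector obj,
                              int model, double center, int alpha_log_link) {
  TrialData d = make_data(y, age, expid, cond, obj, model, center,
                          alpha_log_link);
  int m = draws.nrow();
  NumericMatrix out(d.n, m);
  std::vector<double> par(N_PAR);
  for (int s = 0; s < m; ++s) {
    for (int k = 0; k < N_PAR; ++k) par[k] = draws(s, k);
    for (int i = 0; i < d.n; ++i) out(i, s) = row_prob(d, par.data(), i);
  }
  return out;
}

// log prior: independent normals on main coefficients, hierarchical normals
// on the object offsets with half-normal scale hyperpriors sampled on the
// log scale (Jacobian included)
static double log_prior(const double *par, const double *loc,
                        const double *scale, double re_scale0,
                        double re_scale1, const int *active) {
  double lp = 0.0;
  static const int mains[8] = {0, 1, 2, 3, 4, 5, 32, 33};
  for (int k = 0; k < 8; ++k) {
    int idx = mains[k];
    if (active[idx]) lp += R::dnorm(par[idx], loc[idx], scale[idx], 1);
  }
  double s0 = std::exp(par[30]), s1 = std::exp(par[31]);
  // half-normal(scale) density on sd, plus log|ds/dlog s| = log s
  lp += R::dnorm(s0, 0.0, re_scale0, 1) + M_LN2 + par[30];
  lp += R::dnorm(s1, 0.0, re_scale1, 1) + M_LN2 + par[31];
  for (int j = 0; j < 12; ++j) {
    // standardized offsets (non-centred parameterization)
    lp += R::dnorm(par[6 + j], 0.0, 1.0, 1);
    lp += R::dnorm(par[18 + j], 0.0, 1.0, 1);
  }
  return lp;
}

// which data rows depend on parameter k (by parameter block and variant)
static void rows_for_param(const TrialData &d, int k,
                           std::vector<int> &rows) {
  rows.clear();
  for (int i = 0; i < d.n; ++i) {
    int e = d.expid[i];
    bool dep = false;
    if (k <= 1) {  // alpha
      dep = (e == 1) || (e == 3 && d.model != 4);
    } else if (k <= 3) {  // rho
      dep = (e == 2) || (e == 3 && d.model != 3);
    } else if (k <= 5) {  // theta main
      dep = (e == 1) || (e == 3 && d.model != 4);
    } else if (k <= 29) {  // object offsets
      int j = (k <= 17) ? k - 6 : k - 18;
      dep = (d.obj[i] == j) &&
            ((e == 1) || (e == 3 && d.model != 2 && d.model != 4));
    } else if (k <= 31) {  // offset scales multiply every offset (non-centred)
      dep = (d.obj[i] >= 0) &&
            ((e == 1) || (e == 3 && d.model != 2 && d.model != 4));
    } else {  // phi
      dep = (e == 3 && (d.model == 5 || d.model == 6));
    }
    if (dep) rows.push_back(i);
  }
}

// Adaptive Metropolis-within-Gibbs. Scalar random-walk updates per active
// parameter, proposal scales adapted toward 44% acceptance during warmup
// (Roberts & Rosenthal batch adaptation). Uses R's RNG so set.seed() on the
// R side makes runs reproducible.
// [[Rcpp::export]]
List cpp_fit_mh(IntegerVector y, NumericVector age, IntegerVector expid,
                IntegerVector cond, IntegerVector obj, int model,
                double center, int alpha_log_link,
                NumericVector prior_loc, NumericVector prior_scale,
                double re_scale0, double re_scale1,
                NumericVector init, IntegerVector active,
                int n_warmup, int n_keep, int thin, bool sample_prior) {
  TrialData d = make_data(y, age, expid, cond, obj, model, center,
                          alpha_log_link);
  std::vector<double> par(init.begin(), init.end());
  std::vector<int> act(active.begin(), active.end());
  const double *loc = REAL(prior_loc), *scale = REAL(prior_scale);

  std::vector<int> upd;  // indices updated in one sweep
  for (int k = 0; k < N_PAR; ++k) if (act[k]) upd.push_back(k);
  int n_upd = upd.size();

  std::vector<std::vector<int>> dep(n_upd);
  for (int u = 0; u < n_upd; ++u) rows_for_param(d, upd[u], dep[u]);

  // cached per-row log-likelihood
  std::vector<double> rowll(d.n, 0.0);
  double sum_ll = 0.0;
  if (!sample_prior) {
    for (int i = 0; i < d.n; ++i) {
      rowll[i] = row_loglik(d, par.data(), i);
      sum_ll += rowll[i];
    }
  }
  double lp = log_prior(par.data(), loc, scale, re_scale0, re_scale1,
                        act.data());
  if (!std::isfinite(sum_ll + lp)) stop("initial state has zero posterior");

  std::vector<double> lstep(n_upd, std::log(0.2));
  std::vector<int> acc_batch(n_upd, 0), acc_total(n_upd, 0);
  std::vector<double> prop_row(d.n);

  int n_iter = n_warmup + n_keep * thin;
  NumericMatrix draws(n_keep, N_PAR);
  NumericVector lp_out(n_keep);
  int kept = 0, batch = 0;

  // Haario-style adaptive full-vector proposal over the active block, to
  // traverse the ridge directions (e.g. informativeness versus semantic
  // knowledge) that scalar updates cross slowly. Running moments are
  // accumulated over the whole run; the Cholesky factor is refreshed
  // periodically and the global scale adapted toward 23% acceptance.
  std::vector<double> am_mean(n_upd, 0.0);
  std::vector<double> am_cov(n_upd * n_upd, 0.0);
  std::vector<double> am_chol(n_upd * n_upd, 0.0);
  bool have_chol = false;
  long am_n = 0;
  double am_lscale = std::log(2.38 / std::sqrt((double)n_upd));
  int am_acc_batch = 0, am_trials = 0;

  auto update_moments = [&]() {
    am_n++;
    double w = 1.0 / am_n;
    for (int a = 0; a < n_upd; ++a) {
      double da = par[upd[a]] - am_mean[a];
      am_mean[a] += w * da;
      for (int b = 0; b <= a; ++b) {
        double db = par[upd[b]] - am_mean[b];
        // rank-1 update of the scatter (unnormalised covariance)
        am_cov[a * n_upd + b] += da * db;
      }
    }
  };
  auto refresh_chol = [&]() {
    if (am_n < 10 * n_upd) return;
    std::vector<double> c(n_upd * n_upd);
    double norm = 1.0 / (am_n - 1);
    for (int a = 0; a < n_upd; ++a) {
      for (int b = 0; b <= a; ++b) {
        c[a * n_upd + b] = am_cov[a * n_upd + b] * norm;
      }
      c[a * n_upd + a] += 1e-8;  // ridge for numerical stability
    }
    // lower-triangular Cholesky; bail out if not positive definite
    for (int a = 0; a < n_upd; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = c[a * n_upd + b];
        for (int k = 0; k < b; ++k) {
          s -= am_chol[a * n_upd + k] * am_chol[b * n_upd + k];
        }
        if (a == b) {
          if (s <= 0) return;
          am_chol[a * n_upd + a] = std::sqrt(s);
        } else {
          am_chol[a * n_upd + b] = s / am_chol[b * n_upd + b];
        }
      }
    }
    have_chol = true;
  };

  for (int it = 0; it < n_iter; ++it) {
    for (int u = 0; u < n_upd; ++u) {
      int k = upd[u];
      double old = par[k];
      par[k] = old + std::exp(lstep[u]) * norm_rand();
      double new_lp = log_prior(par.data(), loc, scale, re_scale0, re_scale1,
                                act.data());
      double delta_ll = 0.0;
      const std::vector<int> &rows = dep[u];
      bool ok = std::isfinite(new_lp);
      if (ok && !sample_prior) {
        for (size_t t = 0; t < rows.size(); ++t) {
          double l = row_loglik(d, par.data(), rows[t]);
          if (!std::isfinite(l)) { ok = false; break; }
          prop_row[rows[t]] = l;
          delta_ll += l - rowll[rows[t]];
        }
      }
      double log_ratio = ok ? (new_lp - lp + delta_ll) : R_NegInf;
      if (ok && std::log(unif_rand()) < log_ratio) {
        lp = new_lp;
        sum_ll += delta_ll;
        if (!sample_prior) {
          for (size_t t = 0; t < rows.size(); ++t) {
            rowll[rows[t]] = prop_row[rows[t]];
          }
        }
        acc_batch[u]++; acc_total[u]++;
      } else {
        par[k] = old;
      }
    }
    // joint proposals over the whole active block (twice per sweep: a block
    // move costs a fraction of the scalar sweep and drives the ridge mixing)
    update_moments();
    if ((it + 1) % 100 == 0) refresh_chol();
    for (int rep = 0; rep < 2 && have_chol; ++rep) {
      am_trials++;
      std::vector<double> old_par(par), z(n_upd);
      for (int a = 0; a < n_upd; ++a) z[a] = norm_rand();
      double s = std::exp(am_lscale);
      for (int a = 0; a < n_upd; ++a) {
        double step = 0.0;
        for (int b = 0; b <= a; ++b) step += am_chol[a * n_upd + b] * z[b];
        par[upd[a]] += s * step;
      }
      double new_lp = log_prior(par.data(), loc, scale, re_scale0, re_scale1,
                                act.data());
      double new_sum = 0.0;
      bool ok = std::isfinite(new_lp);
      if (ok && !sample_prior) {
        for (int i = 0; i < d.n; ++i) {
          prop_row[i] = row_loglik(d, par.data(), i);
          if (!std::isfinite(prop_row[i])) { ok = false; break; }
          new_sum += prop_row[i];
        }
      }
      if (ok && std::log(unif_rand()) < (new_lp - lp + new_sum - sum_ll)) {
        lp = new_lp;
        sum_ll = new_sum;
        if (!sample_prior) rowll.swap(prop_row);
        am_acc_batch++;
      } else {
        par = old_par;
      }
    }

    if (it < n_warmup && ((it + 1) % 50 == 0)) {
      batch++;
      double gain = std::min(0.5, 5.0 / std::sqrt((double)batch));
      for (int u = 0; u < n_upd; ++u) {
        double rate = acc_batch[u] / 50.0;
        lstep[u] += gain * (rate - 0.44);
        acc_batch[u] = 0;
      }
      if (am_trials > 0) {
        am_lscale += gain * (am_acc_batch / (double)am_trials - 0.23);
        am_acc_batch = 0; am_trials = 0;
      }
    }
    if (it >= n_warmup && ((it - n_warmup + 1) % thin == 0)) {
      for (int k = 0; k < N_PAR; ++k) draws(kept, k) = par[k];
      lp_out[kept] = lp + sum_ll;
      kept++;
    }
  }

  NumericVector acc(n_upd);
  for (int u = 0; u < n_upd; ++u) acc[u] = acc_total[u] / (double)n_iter;
  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["accept"] = acc, _["updated"] = wrap(upd));
}
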