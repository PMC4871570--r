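// Negative-binomial (NB2) GLM with log link: IRLS for the coefficients
// alternating with maximum-likelihood Newton updates of the size parameter
// theta, plus an exhaustive all-subsets AICc evaluator used by the
// model-averaging engine (thousands to millions of fits per analysis).
//
// Performance notes: because the responses are integer counts, the
// digamma/trigamma/lgamma differences in the theta score reduce to exact
// finite sums over the count tail frequencies c_j = #{y_i > j}
// (digamma(y+t) - digamma(t) = sum_{j<y} 1/(t+j)), which avoids special
// functions in the hot loop; subset fits are warm-started from the fit of
// the parent subset (the subset with the highest-order predictor removed).
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_MAX = 30.0;

struct CountStats {
  arma::vec y;
  std::vector<double> cj;   // tail counts: cj[j] = #{y_i > j}
  double lgam_y1;           // sum lgamma(y_i + 1), constant per response
  double ysum;
};

static CountStats make_stats(const arma::vec& y) {
  CountStats st;
  st.y = y;
  int maxy = 0;
  st.lgam_y1 = 0.0;
  st.ysum = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    maxy = std::max(maxy, (int)y[i]);
    st.lgam_y1 += R::lgammafn(y[i] + 1.0);
    st.ysum += y[i];
  }
  st.cj.assign(maxy, 0.0);
  for (arma::uword i = 0; i < y.n_elem; ++i)
    for (int j = 0; j < (int)y[i]; ++j) st.cj[j] += 1.0;
  return st;
}

// sum_i [lgamma(y_i + th) - lgamma(th)] = sum_j c_j log(th + j)
static double lgamma_diff_sum(const CountStats& st, double th) {
  double s = 0.0;
  for (size_t j = 0; j < st.cj.size(); ++j)
    s += st.cj[j] * std::log(th + (double)j);
  return s;
}

static double nb_loglik(const CountStats& st, const arma::vec& mu, double th) {
  double ll = lgamma_diff_sum(st, th) - st.lgam_y1;
  const double lth = std::log(th);
  for (arma::uword i = 0; i < st.y.n_elem; ++i) {
    double ls = std::log(th + mu[i]);
    ll += th * (lth - ls);
    if (st.y[i] > 0.0) ll += st.y[i] * (std::log(mu[i]) - ls);
  }
  return ll;
}

static double pois_loglik(const CountStats& st, const arma::vec& mu) {
  double ll = -st.lgam_y1;
  for (arma::uword i = 0; i < st.y.n_elem; ++i) {
    ll += -mu[i];
    if (st.y[i] > 0.0) ll += st.y[i] * std::log(mu[i]);
  }
  return ll;
}

// ML updates for theta given mu (at most `steps` per call; the outer
// alternation drives overall convergence). Safeguarded Newton on
// u = log(theta): where the profile is not locally concave (common for
// sparse responses far from the optimum) a bounded fixed step in the score
// direction is taken instead, so theta always moves while the score is
// non-zero. theta is clamped to [1e-5, theta_cap].
static const double THETA_MIN = 1e-5;

static double theta_update(const CountStats& st, const arma::vec& mu,
                           double th, double theta_cap, int steps) {
  const arma::uword n = st.y.n_elem;
  double u = std::log(th);
  const double u_min = std::log(THETA_MIN), u_max = std::log(theta_cap);
  for (int it = 0; it < steps; ++it) {
    // digamma/trigamma differences as exact rational sums
    double sc_dg = 0.0, sc_tg = 0.0;
    for (size_t j = 0; j < st.cj.size(); ++j) {
      double d = th + (double)j;
      sc_dg += st.cj[j] / d;
      sc_tg -= st.cj[j] / (d * d);
    }
    double score = sc_dg + n * (std::log(th) + 1.0);
    double dscore = sc_tg + n / th;
    for (arma::uword i = 0; i < n; ++i) {
      double s = mu[i] + th;
      score  += -std::log(s) - (st.y[i] + th) / s;
      dscore += -1.0 / s - (mu[i] - st.y[i]) / (s * s);
    }
    if (!std::isfinite(score)) break;
    double score_u = score * th;
    double dscore_u = dscore * th * th + score * th;
    double du;
    if (std::isfinite(dscore_u) && dscore_u < 0.0)
      du = -score_u / dscore_u;                 // Newton in log-theta
    else
      du = (score_u > 0.0) ? 0.7 : -0.7;        // fallback: walk the score
    if (du > 2.0) du = 2.0;
    if (du < -2.0) du = -2.0;
    u += du;
    if (u >= u_max) return theta_cap;
    if (u < u_min) u = u_min;
    th = std::exp(u);
    if (std::fabs(du) < 1e-8) break;
  }
  return th;
}

// beta-dependent part of the log-likelihood at fixed theta (the
// lgamma(theta) terms are constant within IRLS and omitted)
static double beta_crit(const arma::vec& y, const arma::vec& mu, double th) {
  double c = 0.0;
  if (th >= 1e12) {                       // Poisson limit
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      c += -mu[i];
      if (y[i] > 0.0) c += y[i] * std::log(mu[i]);
    }
  } else {
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      double ls = std::log(th + mu[i]);
      c += -th * ls;
      if (y[i] > 0.0) c += y[i] * (std::log(mu[i]) - ls);
    }
  }
  return c;
}

// IRLS for beta given theta (or the Poisson limit when theta >= 1e12),
// with step-halving so the likelihood never decreases: rare species with
// large working residuals would otherwise overshoot onto the linear-
// predictor clamp and get trapped there by their own enormous weights.
// Convergence is judged on the likelihood plateau, not on beta, which may
// legitimately diverge under quasi-separation.
static bool irls_beta(const arma::vec& y, const arma::mat& X, double th,
                      arma::vec& beta, arma::vec& mu, int maxit, double tol) {
  const arma::uword n = X.n_rows;
  arma::vec eta = arma::clamp(X * beta, -ETA_MAX, ETA_MAX);
  mu = arma::exp(eta);
  double crit = beta_crit(y, mu, th);
  int stall = 0;
  for (int it = 0; it < maxit; ++it) {
    arma::vec w(n), z(n);
    for (arma::uword i = 0; i < n; ++i) {
      double m = mu[i];
      w[i] = (th >= 1e12) ? m : m / (1.0 + m / th);
      z[i] = eta[i] + (y[i] - m) / m;
    }
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, A, b, arma::solve_opts::likely_sympd +
                                          arma::solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) return false;
    arma::vec dir = beta_new - beta;
    double step = 1.0, crit_new = R_NegInf;
    arma::vec beta_try, mu_try;
    for (int h = 0; h < 12; ++h) {
      beta_try = beta + step * dir;
      mu_try = arma::exp(arma::clamp(X * beta_try, -ETA_MAX, ETA_MAX));
      crit_new = beta_crit(y, mu_try, th);
      if (std::isfinite(crit_new) && crit_new >= crit - 1e-12) break;
      step *= 0.5;
    }
    if (!std::isfinite(crit_new) || crit_new < crit) return true;  // stuck
    beta = beta_try;
    mu = mu_try;
    eta = arma::clamp(X * beta, -ETA_MAX, ETA_MAX);
    double gain = crit_new - crit;
    crit = crit_new;
    if (gain < tol * (std::fabs(crit_new) + 1e-3)) return true;
    // separation creep: likelihood still inching along a flat ridge
    if (gain < 1e-6) { if (++stall >= 2) return true; } else stall = 0;
  }
  return false;
}

struct NBFit {
  arma::vec beta;
  arma::vec mu;
  double theta;
  double loglik;
  bool converged;
  bool boundary;   // all-zero response: intercept at the lower boundary
};

static NBFit nb_fit_core(const CountStats& st, const arma::mat& X,
                         double theta_cap, double tol, int maxit,
                         const arma::vec* beta0 = nullptr,
                         double theta0 = 1.0) {
  NBFit f;
  const arma::uword n = X.n_rows, p = X.n_cols;
  f.boundary = false;
  if (st.ysum == 0.0) {
    f.beta = arma::vec(p, arma::fill::zeros);
    f.beta[0] = std::log(1e-8);
    f.mu = arma::vec(n, arma::fill::value(1e-8));
    f.theta = theta_cap;
    f.loglik = 0.0;
    f.converged = false;
    f.boundary = true;
    return f;
  }
  arma::vec mu;
  double th;
  if (beta0 != nullptr) {
    f.beta = *beta0;
    th = theta0;
    irls_beta(st.y, X, (th >= theta_cap) ? 1e14 : th, f.beta, mu, 50, tol);
  } else {
    f.beta = arma::vec(p, arma::fill::zeros);
    f.beta[0] = std::log(std::max(arma::mean(st.y), 1e-4));
    irls_beta(st.y, X, 1e14, f.beta, mu, 15, 1e-6);  // Poisson warm-up
    th = 1.0;
  }
  double ll_old = R_NegInf;
  f.converged = false;
  int stall = 0;
  for (int outer = 0; outer < maxit; ++outer) {
    th = theta_update(st, mu, th, theta_cap, 5);
    double th_eff = (th >= theta_cap) ? 1e14 : th;
    irls_beta(st.y, X, th_eff, f.beta, mu, 50, tol);
    double ll = (th >= theta_cap) ? pois_loglik(st, mu) : nb_loglik(st, mu, th);
    double dll = std::fabs(ll - ll_old);
    ll_old = ll;
    if (dll < tol * (std::fabs(ll) + 1e-3)) {
      f.converged = true;
      break;
    }
    // plateau guard: degenerate responses (e.g. single presences) leave
    // theta wandering on a flat profile with ~1e-6 likelihood wiggles
    stall = (dll < 1e-6) ? stall + 1 : 0;
    if (stall >= 3) {
      f.converged = true;
      break;
    }
  }
  f.mu = mu;
  f.theta = th;
  f.loglik = ll_old;
  return f;
}

// [[Rcpp::export(name = "C_nb_fit")]]
List C_nb_fit(const arma::vec& y, const arma::mat& X,
              double theta_cap = 1e8, double tol = 1e-8, int maxit = 200) {
  CountStats st = make_stats(y);
  NBFit f = nb_fit_core(st, X, theta_cap, tol, maxit);
  // covariance of beta at fixed theta (expected information, glm convention)
  arma::mat V(X.n_cols, X.n_cols, arma::fill::value(NA_REAL));
  if (!f.boundary) {
    arma::vec w(X.n_rows);
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      double m = f.mu[i];
      w[i] = (f.theta >= theta_cap) ? m : m / (1.0 + m / f.theta);
    }
    arma::mat A = X.t() * (X.each_col() % w);
    arma::mat Vi;
    if (arma::inv_sympd(Vi, A)) V = Vi;
  }
  return List::create(_["coefficients"] = f.beta,
                      _["theta"] = f.theta,
                      _["loglik"] = f.loglik,
                      _["fitted"] = f.mu,
                      _["vcov"] = V,
                      _["converged"] = f.converged,
                      _["boundary"] = f.boundary);
}

// AICc for every predictor subset, summed over the columns of Y.
// Y: n x s response matrix (s = 1 for univariate richness mode);
// Xpred: n x p predictor matrix (no intercept column);
// subsets: list of 0-based integer vectors indexing columns of Xpred.
// k per species-level fit = 1 (intercept) + |subset| + 1 (theta).
// Returns NA for a subset whenever the AICc correction is undefined
// (n <= k + 1).
// [[Rcpp::export(name = "C_nb_aicc_subsets")]]
NumericVector C_nb_aicc_subsets(const arma::mat& Y, const arma::mat& Xpred,
                                const List& subsets, double theta_cap = 1e8,
                                double tol = 1e-8, int maxit = 200) {
  const arma::uword n = Y.n_rows, s = Y.n_cols;
  const int m = subsets.size();
  NumericVector out(m, 0.0);
  std::vector<std::vector<int>> idxs(m);
  std::vector<long long> masks(m);
  std::vector<double> kpar(m);
  for (int j = 0; j < m; ++j) {
    IntegerVector idx = subsets[j];
    idxs[j] = as<std::vector<int>>(idx);
    long long mask = 0;
    for (int v : idxs[j]) mask |= (1LL << v);
    masks[j] = mask;
    kpar[j] = 2.0 + idxs[j].size();
    if ((double)n <= kpar[j] + 1.0) out[j] = NA_REAL;
  }
  struct Cached { arma::vec beta; double theta; };
  for (arma::uword sp = 0; sp < s; ++sp) {
    CountStats st = make_stats(Y.col(sp));
    std::unordered_map<long long, Cached> cache;
    cache.reserve(m);
    for (int j = 0; j < m; ++j) {
      if (NumericVector::is_na(out[j])) continue;
      const size_t q = idxs[j].size();
      arma::mat X(n, q + 1);
      X.col(0).ones();
      for (size_t c = 0; c < q; ++c) X.col(c + 1) = Xpred.col(idxs[j][c]);
      NBFit f;
      // warm start from the subset with the last predictor dropped
      long long parent = -1;
      if (q > 0) parent = masks[j] & ~(1LL << idxs[j][q - 1]);
      auto hit = (parent >= 0) ? cache.find(parent) : cache.end();
      if (hit != cache.end() && hit->second.beta.n_elem == q) {
        arma::vec b0(q + 1, arma::fill::zeros);
        b0.head(q) = hit->second.beta;
        f = nb_fit_core(st, X, theta_cap, tol, maxit, &b0, hit->second.theta);
      } else {
        f = nb_fit_core(st, X, theta_cap, tol, maxit);
      }
      cache[masks[j]] = Cached{f.beta, f.theta};
      double k = kpar[j];
      out[j] += -2.0 * f.loglik + 2.0 * k + 2.0 * k * (k + 1.0) / (n - k - 1.0);
    }
  }
  return out;
}
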