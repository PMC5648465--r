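#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// L1-penalised binomial regression by IRLS + cyclic coordinate descent
// (the penalised-GLM architecture of Friedman, Hastie & Tibshirani):
// IRLS forms the weighted least-squares working problem at the current
// linear predictor and the inner loop solves it by coordinate descent with
// residual updates (O(n) per step, no exponentials), restricted to an
// active set. Once IRLS converges on the active set, one exact-score pass
// (1/n) X'(p - y) over all columns certifies the KKT conditions of the true
// objective; violators join the active set and the cycle repeats. Columns
// of X are expected standardized (mean 0, population sd 1); unpenalised
// columns have penalty factor 0.

static inline double soft(double u, double g) {
  if (u > g) return u - g;
  if (u < -g) return u + g;
  return 0.0;
}

static inline double logistic(double eta) {
  if (eta > 0) return 1.0 / (1.0 + std::exp(-eta));
  const double e = std::exp(eta);
  return e / (1.0 + e);
}

struct WorkState {
  std::vector<double> eta, prob, w, r, wx2;
  std::vector<char> in_active;
  std::vector<int> active;
  void init(int n, int p) {
    eta.assign(n, 0.0);
    prob.assign(n, 0.5);
    w.assign(n, 0.25);
    r.assign(n, 0.0);
    wx2.assign(p, 0.25);
    in_active.assign(p, 0);
    active.clear();
    active.reserve(p);
  }
  void seed_active(const double* beta, const double* pf, int p,
                   const double* hint) {
    std::fill(in_active.begin(), in_active.end(), 0);
    active.clear();
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0 || pf[j] == 0.0 || (hint && hint[j] != 0.0)) {
        in_active[j] = 1;
        active.push_back(j);
      }
  }
};

// IRLS + CD restricted to the current active set; returns 0 / -1 (cap hit)
static int irls_active(const double* X, const double* y, const double* pf,
                       int n, double lambda, double tol, int maxit, double& b0,
                       double* beta, WorkState& st) {
  const double wmin = 1e-5;
  for (int outer = 0; outer < 100; ++outer) {
    double sw = 0.0;
    for (int i = 0; i < n; ++i) {
      const double pi = logistic(st.eta[i]);
      double wi = pi * (1.0 - pi);
      if (wi < wmin) wi = wmin;
      st.w[i] = wi;
      st.r[i] = (y[i] - pi) / wi; // working residual z - eta
      sw += wi;
    }
    // curvature terms for the active columns at these weights
    for (size_t k = 0; k < st.active.size(); ++k) {
      const int j = st.active[k];
      const double* xj = X + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += st.w[i] * xj[i] * xj[i];
      st.wx2[j] = s / n;
    }
    double outer_change = 0.0;
    for (int sweep = 0; sweep < maxit; ++sweep) {
      double maxd = 0.0;
      { // intercept
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += st.w[i] * st.r[i];
        const double d = num / sw;
        if (std::fabs(d) > 1e-13) {
          b0 += d;
          for (int i = 0; i < n; ++i) st.r[i] -= d;
        }
        if (std::fabs(d) > maxd) maxd = std::fabs(d);
      }
      for (size_t k = 0; k < st.active.size(); ++k) {
        const int j = st.active[k];
        const double* xj = X + (size_t)j * n;
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += st.w[i] * xj[i] * st.r[i];
        num = num / n + st.wx2[j] * beta[j];
        const double bn = (pf[j] > 0.0) ? soft(num, lambda * pf[j]) / st.wx2[j]
                                        : num / st.wx2[j];
        const double d = bn - beta[j];
        if (std::fabs(d) > 1e-13) {
          beta[j] = bn;
          for (int i = 0; i < n; ++i) st.r[i] -= d * xj[i];
        }
        if (std::fabs(d) > maxd) maxd = std::fabs(d);
      }
      if (maxd > outer_change) outer_change = maxd;
      if (maxd < tol) break;
      if (sweep == maxit - 1) return -1;
    }
    // refresh the linear predictor from the active support
    std::fill(st.eta.begin(), st.eta.end(), b0);
    for (size_t k = 0; k < st.active.size(); ++k) {
      const int j = st.active[k];
      if (beta[j] == 0.0) continue;
      const double* xj = X + (size_t)j * n;
      const double bj = beta[j];
      for (int i = 0; i < n; ++i) st.eta[i] += bj * xj[i];
    }
    if (outer_change < tol) return 0;
  }
  return -1;
}

// fit one lambda: active-set IRLS + exact KKT entry cycle
static int cd_fit(const double* X, const double* y, const double* pf, int n,
                  int p, double lambda, double tol, int maxit, double& b0,
                  double* beta, WorkState& st, const double* hint) {
  st.seed_active(beta, pf, p, hint);
  for (int round = 0; round < 50; ++round) {
    if (irls_active(X, y, pf, n, lambda, tol, maxit, b0, beta, st) != 0)
      return -1;
    // exact score over all inactive penalised columns
    for (int i = 0; i < n; ++i) st.prob[i] = logistic(st.eta[i]);
    bool clean = true;
    for (int j = 0; j < p; ++j) {
      if (st.in_active[j]) continue;
      const double* xj = X + (size_t)j * n;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += xj[i] * (st.prob[i] - y[i]);
      g /= n;
      if (std::fabs(g) > lambda * pf[j] + 0.25 * tol) {
        st.in_active[j] = 1;
        st.active.push_back(j);
        clean = false;
      }
    }
    if (clean) return 0;
  }
  return -1;
}

// [[Rcpp::export(name = ".lasso_path_cpp")]]
List lasso_path_cpp(const NumericMatrix& X, const NumericVector& y,
                    const NumericVector& pf, const NumericVector& lambda,
                    double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericVector b0v(L);
  NumericMatrix betam(p, L);
  IntegerVector status(L);
  NumericVector dev(L);
  WorkState st;
  st.init(n, p);
  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;
  for (int l = 0; l < L; ++l) {
    status[l] = cd_fit(REAL(X), REAL(y), REAL(pf), n, p, lambda[l], tol,
                       maxit, b0, beta.data(), st, nullptr);
    b0v[l] = b0;
    for (int i = 0; i < n; ++i) st.prob[i] = logistic(st.eta[i]);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double pi = st.prob[i];
      if (pi < 1e-10) pi = 1e-10;
      if (pi > 1 - 1e-10) pi = 1 - 1e-10;
      ll += y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi);
    }
    dev[l] = -2.0 * ll;
    for (int j = 0; j < p; ++j) betam(j, l) = beta[j];
  }
  return List::create(_["beta0"] = b0v, _["beta"] = betam,
                      _["status"] = status, _["deviance"] = dev);
}

// Fit one lambda on the data minus one observation, warm-started from the
// full-data solution at that lambda. The held-out row is excluded by zeroing
// its IRLS weight and residual, so no data copies are made; the quadratic
// curvature terms `wx2` are a fixed preconditioner (the KKT fixed point
// depends only on the gradient, which is recomputed exactly each outer
// iteration and certified over all columns at the end).
static int cd_fit_loo(const double* X, const double* y, const double* pf,
                      int n, int hold, double lambda, double tol, int maxit,
                      double& b0, double* beta, const double* wx2,
                      std::vector<double>& eta, std::vector<double>& w,
                      std::vector<double>& r, std::vector<double>& z,
                      std::vector<char>& in_active, std::vector<int>& active) {
  const double wmin = 1e-5;
  const int neff = n - 1;
  in_active.assign(in_active.size(), 0);
  active.clear();
  const int p = (int)in_active.size();
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0 || pf[j] == 0.0) {
      in_active[j] = 1;
      active.push_back(j);
    }
  for (int round = 0; round < 50; ++round) {
    int status = -1;
    for (int outer = 0; outer < 100; ++outer) {
      double sw = 0.0;
      for (int i = 0; i < n; ++i) {
        const double pi = logistic(eta[i]);
        double wi = pi * (1.0 - pi);
        if (wi < wmin) wi = wmin;
        if (i == hold) {
          w[i] = 0.0;
          r[i] = 0.0;
          z[i] = eta[i];
        } else {
          w[i] = wi;
          r[i] = (y[i] - pi) / wi;
          z[i] = eta[i] + r[i];
          sw += wi;
        }
      }
      double outer_change = 0.0;
      for (int sweep = 0; sweep < maxit; ++sweep) {
        double maxd = 0.0;
        {
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * r[i];
          const double d = num / sw;
          if (std::fabs(d) > 1e-13) {
            b0 += d;
            for (int i = 0; i < n; ++i) r[i] -= d;
          }
          if (std::fabs(d) > maxd) maxd = std::fabs(d);
        }
        for (size_t k = 0; k < active.size(); ++k) {
          const int j = active[k];
          const double* xj = X + (size_t)j * n;
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
          num = num / neff + wx2[j] * beta[j];
          const double bn = (pf[j] > 0.0)
                                ? soft(num, lambda * pf[j]) / wx2[j]
                                : num / wx2[j];
          const double d = bn - beta[j];
          if (std::fabs(d) > 1e-13) {
            beta[j] = bn;
            for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
          }
          if (std::fabs(d) > maxd) maxd = std::fabs(d);
        }
        if (maxd > outer_change) outer_change = maxd;
        if (maxd < tol) break;
        if (sweep == maxit - 1) return -1;
      }
      // eta = z - r, including the held-out row (kept for prediction via
      // explicit dot product, so its entry is never used)
      for (int i = 0; i < n; ++i) eta[i] = z[i] - r[i];
      if (outer_change < tol) {
        status = 0;
        break;
      }
    }
    if (status != 0) return -1;
    // exact KKT over inactive penalised columns (held-out row excluded)
    bool clean = true;
    std::vector<double> res(n);
    for (int i = 0; i < n; ++i)
      res[i] = (i == hold) ? 0.0 : logistic(eta[i]) - y[i];
    for (int j = 0; j < p; ++j) {
      if (in_active[j]) continue;
      const double* xj = X + (size_t)j * n;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += xj[i] * res[i];
      g /= neff;
      if (std::fabs(g) > lambda * pf[j] + 0.25 * tol) {
        in_active[j] = 1;
        active.push_back(j);
        clean = false;
      }
    }
    if (clean) return 0;
  }
  return -1;
}

// Leave-one-out CV: at every lambda, each fold is refit from the full-data
// solution; records the held-out binomial deviance contribution per lambda.
// [[Rcpp::export(name = ".lasso_loocv_cpp")]]
NumericMatrix lasso_loocv_cpp(const NumericMatrix& X, const NumericVector& y,
                              const NumericVector& pf,
                              const NumericVector& lambda,
                              const NumericVector& full_beta0,
                              const NumericMatrix& full_beta, double tol,
                              int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix out(n, L);
  std::vector<double> beta(p), eta(n), eta_full(n), w(n), r(n), z(n), wx2(p);
  std::vector<char> in_active(p, 0);
  std::vector<int> active;
  active.reserve(p);
  for (int l = 0; l < L; ++l) {
    // full-data linear predictor and curvature preconditioner at this lambda
    std::fill(eta_full.begin(), eta_full.end(), full_beta0[l]);
    for (int j = 0; j < p; ++j) {
      const double bj = full_beta(j, l);
      if (bj == 0.0) continue;
      const double* xj = &X(0, j);
      for (int i = 0; i < n; ++i) eta_full[i] += bj * xj[i];
    }
    for (int i = 0; i < n; ++i) {
      const double pi = logistic(eta_full[i]);
      w[i] = std::max(pi * (1.0 - pi), 1e-5);
    }
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
      wx2[j] = std::max(s / n, 1e-4);
    }
    for (int hold = 0; hold < n; ++hold) {
      double b0 = full_beta0[l];
      for (int j = 0; j < p; ++j) beta[j] = full_beta(j, l);
      std::copy(eta_full.begin(), eta_full.end(), eta.begin());
      cd_fit_loo(REAL(X), REAL(y), REAL(pf), n, hold, lambda[l], tol, maxit,
                 b0, beta.data(), wx2.data(), eta, w, r, z, in_active, active);
      double eh = b0;
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) eh += beta[j] * X(hold, j);
      double ph = logistic(eh);
      if (ph < 1e-10) ph = 1e-10;
      if (ph > 1 - 1e-10) ph = 1 - 1e-10;
      out(hold, l) = -2.0 * (y[hold] * std::log(ph) +
                             (1.0 - y[hold]) * std::log(1.0 - ph));
    }
  }
  return out;
}
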