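#include <Rcpp.h>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Penalized logistic regression by IRLS + cyclic coordinate descent on the
// standardized design, over a descending lambda path with warm starts,
// sequential strong-rule screening and (optional) early path truncation.
//
// Objective (per-observation scaling, the usual penalized-GLM convention):
//   -(1/n) sum_i [ y_i eta_i - log(1 + exp(eta_i)) ]
//     + lambda * sum_j pf_j * ( alpha*|b_j| + (1-alpha)/2 * b_j^2 )
// Columns with pf_j = 0 (clinical covariates) and the intercept are never
// shrunk. X must arrive standardized (mean 0, variance 1 with 1/n divisor);
// coefficients are returned on that standardized scale.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double stable_softplus(double eta) {
  return eta > 0 ? eta + std::log1p(std::exp(-eta)) : std::log1p(std::exp(eta));
}

// [[Rcpp::export]]
List enet_logistic_path_cpp(NumericMatrix X, NumericVector y,
                            NumericVector lambdas, double alpha,
                            NumericVector pf, double thresh,
                            int maxit_outer, int maxit_inner,
                            NumericVector beta_init, double b0_init,
                            double fdev, double devmax) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambdas.size();
  const double PMIN = 1e-5;
  const double* xp = REAL(X);  // column-major

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  double b0 = b0_init;

  NumericMatrix beta_out(p, nlam);
  NumericVector b0_out(nlam), obj_out(nlam), dev_out(nlam);
  IntegerVector iters_out(nlam);
  LogicalVector conv_out(nlam);

  std::vector<double> eta(n), w(n), z(n), r(n), vj(p, 0.0), grad(p);
  std::vector<char> in_work(p, 0);
  std::vector<int> work;
  work.reserve(p);

  // negative log-likelihood (sum over observations) at the current fit
  auto nll_current = [&]() {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += y[i] * eta[i] - stable_softplus(eta[i]);
    return -s;
  };
  auto recompute_eta = [&]() {
    for (int i = 0; i < n; ++i) eta[i] = b0;
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0) {
        const double* xj = xp + (size_t)j * n;
        const double bj = beta[j];
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
      }
    }
  };
  // gradient of (1/n) NLL for every column, at the current eta
  auto full_gradient = [&]() {
    std::vector<double> res(n);
    for (int i = 0; i < n; ++i) res[i] = y[i] - 1.0 / (1.0 + std::exp(-eta[i]));
    for (int j = 0; j < p; ++j) {
      const double* xj = xp + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * res[i];
      grad[j] = -s / n;
    }
  };

  recompute_eta();
  const double ybar = std::accumulate(&y[0], &y[0] + n, 0.0) / n;
  const double dev_null =
      -2.0 * n * (ybar * std::log(std::max(ybar, 1e-12)) +
                  (1 - ybar) * std::log(std::max(1 - ybar, 1e-12)));

  int nlam_used = nlam;
  double dev_prev = R_PosInf;

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambdas[l];
    const double lam_prev = (l == 0) ? lam : lambdas[l - 1];

    // sequential strong rule on the gradient at the previous solution
    full_gradient();
    std::fill(in_work.begin(), in_work.end(), 0);
    work.clear();
    const double a_scr = alpha;
    for (int j = 0; j < p; ++j) {
      bool keep = (pf[j] == 0.0) || (beta[j] != 0.0);
      if (!keep) {
        double cut = a_scr * pf[j] * (2.0 * lam - lam_prev);
        keep = std::fabs(grad[j]) >= cut;
      }
      if (keep) { in_work[j] = 1; work.push_back(j); }
    }

    bool converged = false;
    int outer_total = 0;

    while (true) {  // KKT loop: solve on working set, then admit violators
      converged = false;
      for (int outer = 0; outer < maxit_outer; ++outer) {
        ++outer_total;
        // IRLS weights at the current fit
        double sw = 0.0;
        for (int i = 0; i < n; ++i) {
          double pr = 1.0 / (1.0 + std::exp(-eta[i]));
          if (pr < PMIN) pr = PMIN; else if (pr > 1.0 - PMIN) pr = 1.0 - PMIN;
          w[i] = pr * (1.0 - pr);
          z[i] = eta[i] + (y[i] - pr) / w[i];
          r[i] = z[i] - eta[i];
          sw += w[i];
        }
        for (int j : work) {
          const double* xj = xp + (size_t)j * n;
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
          vj[j] = s / n;
        }

        auto update_coord = [&](int j) -> double {
          if (vj[j] <= 0.0) return 0.0;  // constant (all-zero) column
          const double* xj = xp + (size_t)j * n;
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
          num = num / n + vj[j] * beta[j];
          double bj_new;
          if (pf[j] > 0.0) {
            bj_new = soft(num, lam * alpha * pf[j]) /
                     (vj[j] + lam * (1.0 - alpha) * pf[j]);
          } else {
            bj_new = num / vj[j];
          }
          double d = bj_new - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
            beta[j] = bj_new;
            return vj[j] * d * d;
          }
          return 0.0;
        };
        auto update_intercept = [&]() -> double {
          double num0 = 0.0;
          for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
          double d0 = num0 / sw;
          if (d0 == 0.0) return 0.0;
          for (int i = 0; i < n; ++i) r[i] -= d0;
          b0 += d0;
          return sw / n * d0 * d0;
        };

        // coordinate descent with an inner active-set loop
        double max_change = 0.0;
        int inner_used = 0;
        while (true) {
          double dlx = update_intercept();
          for (int j : work) {
            double c = update_coord(j);
            if (c > dlx) dlx = c;
          }
          if (dlx > max_change) max_change = dlx;
          ++inner_used;
          if (dlx < thresh || inner_used >= maxit_inner) break;
          std::vector<int> active;
          active.reserve(work.size());
          for (int j : work)
            if (beta[j] != 0.0 || pf[j] == 0.0) active.push_back(j);
          while (inner_used < maxit_inner) {
            double dax = update_intercept();
            for (int j : active) {
              double c = update_coord(j);
              if (c > dax) dax = c;
            }
            ++inner_used;
            if (dax < thresh) break;
          }
        }
        // eta at the updated coefficients (z - r is the fitted surrogate)
        for (int i = 0; i < n; ++i) eta[i] = z[i] - r[i];
        if (max_change < thresh) { converged = true; break; }
      }

      // KKT check over the excluded columns at the solved fit
      full_gradient();
      int violators = 0;
      for (int j = 0; j < p; ++j) {
        if (in_work[j]) continue;
        if (std::fabs(grad[j]) > lam * alpha * pf[j] * (1.0 + 1e-9)) {
          in_work[j] = 1; work.push_back(j); ++violators;
        }
      }
      if (violators == 0) break;
    }

    // numerical dust at the soft-threshold boundary is exactly zero
    for (int j = 0; j < p; ++j)
      if (pf[j] > 0.0 && std::fabs(beta[j]) < 1e-12) beta[j] = 0.0;

    // divergence guard (quasi-separation at vanishing penalty)
    double bmax = std::fabs(b0);
    for (int j = 0; j < p; ++j)
      if (std::fabs(beta[j]) > bmax) bmax = std::fabs(beta[j]);
    if (bmax > 1e3) {
      if (lam == 0.0) {
        stop("divergence at lambda = 0 (data likely separable); "
             "increase lambda.");
      }
      converged = false;
    }

    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    b0_out[l] = b0;
    iters_out[l] = outer_total;
    conv_out[l] = converged;
    double nll = nll_current();
    double pen = 0.0;
    for (int j = 0; j < p; ++j) {
      pen += pf[j] * (alpha * std::fabs(beta[j]) +
                      0.5 * (1.0 - alpha) * beta[j] * beta[j]);
    }
    obj_out[l] = nll / n + lam * pen;
    dev_out[l] = 2.0 * nll;

    if (fdev > 0 && l >= 1) {  // glmnet-style path truncation
      if (dev_prev - dev_out[l] < fdev * dev_null ||
          1.0 - dev_out[l] / dev_null > devmax) {
        nlam_used = l + 1;
        break;
      }
    }
    dev_prev = dev_out[l];
  }

  return List::create(_["beta"] = beta_out, _["b0"] = b0_out,
                      _["iterations"] = iters_out, _["converged"] = conv_out,
                      _["objective"] = obj_out, _["deviance"] = dev_out,
                      _["nlam_used"] = nlam_used);
}
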