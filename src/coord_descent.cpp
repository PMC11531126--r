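#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the weighted, L1-penalized least-squares
// surrogate of the Cox partial likelihood:
//   min_b  0.5 * sum_i w_i (z_i - x_i'b)^2 + lambda * sum_j pf_j |b_j|
// Active-set iteration: full sweeps alternate with sweeps over the current
// nonzero set until no coordinate moves more than `tol`.
// [[Rcpp::export]]
NumericVector cd_wls_l1_cpp(NumericMatrix Xs, NumericVector w,
                            NumericVector z, double lambda,
                            NumericVector pf, NumericVector beta_init,
                            double tol, int max_sweeps) {
  const int n = Xs.nrow(), p = Xs.ncol();
  NumericVector beta = clone(beta_init);
  std::vector<double> r(n), denom(p);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += Xs(i, j) * beta[j];
    r[i] = z[i] - eta;
  }
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * Xs(i, j) * Xs(i, j);
    denom[j] = s;
  }
  bool full_sweep = true;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double delta_max = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!full_sweep && beta[j] == 0.0) continue;
      if (denom[j] <= 0.0) continue;
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += w[i] * Xs(i, j) * r[i];
      rho += denom[j] * beta[j];
      double thr = lambda * pf[j];
      double bj = 0.0;
      if (rho > thr) bj = (rho - thr) / denom[j];
      else if (rho < -thr) bj = (rho + thr) / denom[j];
      double diff = bj - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= Xs(i, j) * diff;
        beta[j] = bj;
        double ad = std::fabs(diff);
        if (ad > delta_max) delta_max = ad;
      }
    }
    if (delta_max < tol) {
      if (full_sweep) break;      // converged on a verified full sweep
      full_sweep = true;          // active set stable: verify with full sweep
    } else {
      full_sweep = false;         // iterate the active set
    }
  }
  return beta;
}

// Coordinate descent on a precomputed quadratic model (proximal-Newton
// inner problem):
//   min_b  g'(b - beta0) + 0.5 (b - beta0)' H (b - beta0) + lambda sum pf_j |b_j|
// H is the p x p Hessian of the smooth part at beta0, g its gradient.
// [[Rcpp::export]]
NumericVector cd_quad_l1_cpp(NumericMatrix H, NumericVector g,
                             NumericVector beta0, double lambda,
                             NumericVector pf, NumericVector beta_init,
                             double tol, int max_sweeps) {
  const int p = H.ncol();
  NumericVector b = clone(beta_init);
  std::vector<double> v(p);  // v = H (b - beta0)
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += H(j, k) * (b[k] - beta0[k]);
    v[j] = s;
  }
  bool full_sweep = true;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double delta_max = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!full_sweep && b[j] == 0.0) continue;
      double hjj = H(j, j);
      if (hjj <= 0.0) continue;
      double d = g[j] + v[j];
      double rho = hjj * b[j] - d;
      double thr = lambda * pf[j];
      double bj = 0.0;
      if (rho > thr) bj = (rho - thr) / hjj;
      else if (rho < -thr) bj = (rho + thr) / hjj;
      double diff = bj - b[j];
      if (diff != 0.0) {
        for (int k = 0; k < p; ++k) v[k] += H(k, j) * diff;
        b[j] = bj;
        double ad = std::fabs(diff);
        if (ad > delta_max) delta_max = ad;
      }
    }
    if (delta_max < tol) {
      if (full_sweep) break;
      full_sweep = true;
    } else {
      full_sweep = false;
    }
  }
  return b;
}
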