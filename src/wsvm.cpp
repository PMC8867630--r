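#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dual solver for a linear max-margin classifier with per-sample box
// constraints (sample i may carry its own misclassification budget ub_i):
//
//   min_a  1/2 a'Qa - e'a   s.t.  0 <= a_i <= ub_i,  y'a = 0,
//   Q_ij = y_i y_j <x_i, x_j>
//
// solved by sequential minimal optimization with second-order working-set
// selection. The Gram matrix of the full sample is passed once; `idx`
// (1-based) selects the active subsample so the caller can re-fit many faces
// against subsets without copying kernels. `alpha_init` (optional) warm
// starts the solve; it is clipped to the boxes and repaired to satisfy the
// equality constraint.
//
// Returns alpha, the intercept b (decision f(x) = sum_i a_i y_i K(x_i,x) + b),
// the dual objective, the final KKT gap and the iteration count.
// [[Rcpp::export]]
List wsvm_smo(NumericMatrix gram, IntegerVector idx, NumericVector y,
              NumericVector ub, double tol = 1e-3, int max_iter = 200000,
              Nullable<NumericVector> alpha_init = R_NilValue) {
  const int n = idx.size();
  if (n < 2) stop("need at least two active samples");
  const double TAU = 1e-12;
  const int N = gram.nrow();
  const double *G0 = gram.begin();

  std::vector<int> gi(n);
  for (int t = 0; t < n; ++t) gi[t] = idx[t] - 1;

  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  // column gi[i] of the full Gram, i.e. K(., x_i); rows indexed by gi[t]
  auto kcol = [&](int i) -> const double * { return G0 + (size_t)N * gi[i]; };

  bool warm = false;
  if (alpha_init.isNotNull()) {
    NumericVector a0(alpha_init);
    if ((int)a0.size() == n) {
      warm = true;
      double viol = 0.0;
      for (int t = 0; t < n; ++t) {
        alpha[t] = std::min(std::max(a0[t], 0.0), ub[t]);
        viol += y[t] * alpha[t];
      }
      for (int t = 0; t < n && std::abs(viol) > 1e-12; ++t) {
        double change = -y[t] * viol;                  // desired move
        double nv = std::min(std::max(alpha[t] + change, 0.0), ub[t]);
        viol += y[t] * (nv - alpha[t]);
        alpha[t] = nv;
      }
      // G = Q alpha - 1, accumulated over support vectors only
      for (int s = 0; s < n; ++s) {
        if (alpha[s] <= 0) continue;
        const double *ks = kcol(s);
        const double c = alpha[s] * y[s];
        for (int t = 0; t < n; ++t) G[t] += y[t] * c * ks[gi[t]];
      }
    }
  }
  (void)warm;

  int iter = 0;
  double gap = std::numeric_limits<double>::infinity();
  for (iter = 0; iter < max_iter; ++iter) {
    // first index: maximal -y_i G_i over I_up
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    int i = -1;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0) ? (alpha[t] < ub[t]) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0)     : (alpha[t] < ub[t]);
      const double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) Gmin = v;
    }
    gap = Gmax - Gmin;
    if (i < 0 || gap < tol) break;

    // second index: I_low candidate with best second-order gain
    const double *ki = kcol(i);
    const double Qii = ki[gi[i]];
    int j = -1;
    double best_gain = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < ub[t]);
      if (!low) continue;
      const double diff = Gmax + y[t] * G[t];          // Gmax - (-y_t G_t)
      if (diff <= 0) continue;
      double a = Qii + (G0 + (size_t)N * gi[t])[gi[t]] - 2.0 * ki[gi[t]];
      if (a <= 0) a = TAU;
      const double gain = diff * diff / a;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) break;

    const double *kj = kcol(j);
    const double Qjj = kj[gi[j]];
    const double Qij = ki[gi[j]];
    const double ai_old = alpha[i], aj_old = alpha[j];

    // curvature along the feasible direction is ||x_i - x_j||^2 in both
    // label configurations (Q-space signs cancel against the kernel)
    double quad = Qii + Qjj - 2.0 * Qij;
    if (quad <= 0) quad = TAU;
    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > ub[i] - ub[j]) {
        if (alpha[i] > ub[i]) { alpha[i] = ub[i]; alpha[j] = ub[i] - diff; }
      } else {
        if (alpha[j] > ub[j]) { alpha[j] = ub[j]; alpha[i] = ub[j] + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > ub[i]) {
        if (alpha[i] > ub[i]) { alpha[i] = ub[i]; alpha[j] = sum - ub[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > ub[j]) {
        if (alpha[j] > ub[j]) { alpha[j] = ub[j]; alpha[i] = sum - ub[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = (alpha[i] - ai_old) * y[i];
    const double daj = (alpha[j] - aj_old) * y[j];
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (ki[gi[t]] * dai + kj[gi[t]] * daj);
    }
  }

  // intercept: average of y_t G_t over free support vectors, else midpoint
  double ubound = std::numeric_limits<double>::infinity();
  double lbound = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0; int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= ub[t] - 1e-12 * (1.0 + ub[t])) {
      if (y[t] < 0) ubound = std::min(ubound, yG);
      else          lbound = std::max(lbound, yG);
    } else if (alpha[t] <= 1e-15) {
      if (y[t] > 0) ubound = std::min(ubound, yG);
      else          lbound = std::max(lbound, yG);
    } else {
      sum_free += yG; ++n_free;
    }
  }
  double rho;
  if (n_free > 0) rho = sum_free / n_free;
  else rho = (ubound + lbound) / 2.0;

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = -rho,
                      _["objective"] = obj,
                      _["gap"] = gap,
                      _["iterations"] = iter);
}
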