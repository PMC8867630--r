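#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// L1-loss linear C-SVM by dual coordinate descent (the liblinear scheme):
//
//   min_w 1/2 ||w||^2 + C sum_i max(0, 1 - y_i w'x_i)
//
// with the bias handled by an augmented constant feature (the caller
// appends it), solved by cyclic coordinate updates on the dual with
// projected-gradient screening. Deterministic: coordinates are visited in
// a fixed shuffled order derived from `seed`.
// [[Rcpp::export]]
List linear_svc_cd(NumericMatrix X, NumericVector y, double C,
                   double tol = 0.01, int max_epochs = 500, int seed = 1) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), Qii(n);

  // samples stored contiguously (row-major copy) so the per-coordinate
  // inner products stream through cache
  std::vector<double> Xt((size_t)n * d);
  const double *xp = X.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    double *row = &Xt[(size_t)i * d];
    for (int j = 0; j < d; ++j) {
      row[j] = xp[i + (size_t)n * j];
      s += row[j] * row[j];
    }
    Qii[i] = s > 0 ? s : 1e-12;
  }

  // fixed visiting order from a small LCG (deterministic given seed)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long state = (unsigned long)seed * 2654435761UL + 1UL;
  for (int i = n - 1; i > 0; --i) {
    state = state * 6364136223846793005UL + 1442695040888963407UL;
    int j = (int)(state % (unsigned long)(i + 1));
    std::swap(order[i], order[j]);
  }

  int epoch = 0;
  double max_pg = 0.0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      const double *xi = &Xt[(size_t)i * d];
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha[i];
        double a = a_old - g / Qii[i];
        if (a < 0.0) a = 0.0;
        else if (a > C) a = C;
        alpha[i] = a;
        const double delta = (a - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
        }
      }
    }
    if (max_pg < tol) break;
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch,
                      _["max_pg"] = max_pg);
}
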