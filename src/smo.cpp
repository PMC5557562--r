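#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Sequential minimal optimization for the two-class C-SVC dual with an RBF
// kernel. Deterministic maximal-violating-pair working-set selection, no
// shrinking; the full kernel matrix is held in memory (desk-scale n).
//
// Dual: min 0.5 a'Qa - e'a, 0 <= a_i <= C, y'a = 0, Q_ij = y_i y_j K_ij.
//
// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
               double tol = 1e-3, double max_iter = 5e5) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("label length does not match rows");
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive");

  std::vector<double> K((size_t)n * n);
  std::vector<double> sq(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = 0; k < d; ++k) { double v = X(i, k); s += v * v; }
    sq[i] = s;
  }
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double dot = 0;
      for (int k = 0; k < d; ++k) dot += X(i, k) * X(j, k);
      double v = std::exp(-gamma * std::max(0.0, sq[i] + sq[j] - 2.0 * dot));
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> a(n, 0.0), G(n, -1.0);
  double iter = 0;
  double m = 0, M = 0;
  bool converged = false;
  while (iter < max_iter) {
    int i = -1, j = -1;
    m = -1e300; M = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      bool lo = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) { converged = true; break; }
    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j]
                 - 2.0 * K[(size_t)i * n + j];
    if (eta < 1e-12) eta = 1e-12;
    double step = (m - M) / eta;
    // direction a_i += y_i t, a_j -= y_j t keeps y'a constant
    step = std::min(step, (y[i] > 0) ? (C - a[i]) : a[i]);
    step = std::min(step, (y[j] > 0) ? a[j] : (C - a[j]));
    double dai = y[i] * step, daj = -y[j] * step;
    a[i] += dai; a[j] += daj;
    a[i] = std::min(std::max(a[i], 0.0), C);
    a[j] = std::min(std::max(a[j], 0.0), C);
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * dai
                      + y[j] * K[(size_t)t * n + j] * daj);
    }
    iter += 1;
  }

  // Intercept: f(x) = sum_i a_i y_i K(x_i, x) + b; for free SVs
  // b = -y_i G_i, otherwise midpoint of the feasibility interval.
  double bsum = 0; int bcnt = 0;
  for (int t = 0; t < n; ++t) {
    if (a[t] > 1e-8 && a[t] < C - 1e-8) { bsum += -y[t] * G[t]; ++bcnt; }
  }
  double b = bcnt ? bsum / bcnt : (m + M) / 2.0;

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
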