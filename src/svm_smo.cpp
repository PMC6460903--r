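// Minimal C-SVC solver for the RBF kernel: SMO with maximal-violating-pair
// working-set selection. Solves
//   min 0.5 a'Qa - e'a  s.t. 0 <= a_i <= C, y'a = 0,  Q_ij = y_i y_j K_ij
// Correctness is asserted in the test suite via the KKT conditions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rbf(const double* a, const double* b, int p, double gamma) {
  double s = 0.0;
  for (int k = 0; k < p; k++) { double d = a[k] - b[k]; s += d * d; }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
                   double eps = 1e-3, int max_iter = 0) {
  const int n = X.nrow(), p = X.ncol();
  if (max_iter <= 0) max_iter = std::max(200000, 200 * n);
  std::vector<double> xr((size_t)n * p);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < p; k++) xr[(size_t)i * p + k] = X(i, k);
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; i++) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; j++) {
      double v = rbf(&xr[(size_t)i * p], &xr[(size_t)j * p], p, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  double m = 0.0, M = 0.0;
  int iter = 0;
  for (iter = 0; iter < max_iter; iter++) {
    m = -1e300; M = 1e300;
    int i = -1, j = -1;
    for (int t = 0; t < n; t++) {
      double v = -y[t] * G[t];
      bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < eps) break;
    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    // E_i - E_j = y_i G_i - y_j G_j; two-variable analytic solve with box
    double aj_new = aj + y[j] * (y[i] * G[i] - y[j] * G[j]) / eta;
    double L, H;
    if (y[i] * y[j] < 0) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else                 { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    double dai = ai_new - ai, daj = aj_new - aj;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) break;
    alpha[i] = ai_new; alpha[j] = aj_new;
    for (int t = 0; t < n; t++)
      G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * dai +
                      y[j] * K[(size_t)t * n + j] * daj);
  }
  // bias: -y_t G_t equals b exactly at free support vectors
  double b = 0.0; int nfree = 0;
  for (int t = 0; t < n; t++) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { b += -y[t] * G[t]; nfree++; }
  }
  if (nfree > 0) b /= nfree; else b = (m + M) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m - M);
}

// [[Rcpp::export]]
NumericVector svm_smo_decision(NumericMatrix Xtr, NumericVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xte) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nt = Xte.nrow();
  std::vector<double> xr((size_t)n * p), xt((size_t)nt * p);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < p; k++) xr[(size_t)i * p + k] = Xtr(i, k);
  for (int i = 0; i < nt; i++)
    for (int k = 0; k < p; k++) xt[(size_t)i * p + k] = Xte(i, k);
  NumericVector out(nt);
  for (int i = 0; i < nt; i++) {
    double f = b;
    for (int s = 0; s < n; s++) {
      if (alpha[s] <= 0) continue;
      f += alpha[s] * y[s] * rbf(&xr[(size_t)s * p], &xt[(size_t)i * p], p, gamma);
    }
    out[i] = f;
  }
  return out;
}
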