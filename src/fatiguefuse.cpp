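#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
//   min 1/2 sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t. 0 <= a_i <= C, sum_i y_i a_i = 0
// Working-set selection by the maximal-violating-pair rule; returns the dual
// variables, the bias, the iteration count and the final KKT gap.
// [[Rcpp::export(name = "cpp_smo_solve")]]
List cpp_smo_solve(NumericMatrix K, NumericVector y, double C,
                   double tol = 1e-6, int max_iter = 1000000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), F(n, 0.0);
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    m_up = -1e300; m_low = 1e300;
    for (int t = 0; t < n; ++t) {
      double g = y[t] - F[t];  // -E_t
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && g > m_up) { m_up = g; i = t; }
      if (in_low && g < m_low) { m_low = g; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) break;

    double Ei = F[i] - y[i], Ej = F[j] - y[j];
    double s = y[i] * y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    double L, H;
    if (s > 0) { L = std::max(0.0, alpha[i] + alpha[j] - C);
                 H = std::min(C, alpha[i] + alpha[j]); }
    else       { L = std::max(0.0, alpha[j] - alpha[i]);
                 H = std::min(C, C + alpha[j] - alpha[i]); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = alpha[i] + s * (alpha[j] - aj_new);
    double di = (ai_new - alpha[i]) * y[i];
    double dj = (aj_new - alpha[j]) * y[j];
    if (std::abs(di) < 1e-15 && std::abs(dj) < 1e-15) break;  // numerically stuck
    for (int t = 0; t < n; ++t) F[t] += di * K(i, t) + dj * K(j, t);
    alpha[i] = ai_new;
    alpha[j] = aj_new;
  }
  double b = (m_up + m_low) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m_up - m_low);
}

// RBF kernel matrix exp(-||x_i - z_j||^2 / sigma^2) between row sets.
// [[Rcpp::export(name = "cpp_rbf_kernel")]]
NumericMatrix cpp_rbf_kernel(NumericMatrix X, NumericMatrix Z, double sigma) {
  const int n = X.nrow(), m = Z.nrow(), p = X.ncol();
  const double inv = 1.0 / (sigma * sigma);
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = X(i, k) - Z(j, k);
        d2 += d * d;
      }
      K(i, j) = std::exp(-d2 * inv);
    }
  return K;
}

// LMS adaptive canceler inner loop with a quadrature reference pair.
// Returns the error signal (input minus the tracked interference estimate)
// and the final weights.
// [[Rcpp::export(name = "smo_lms")]]
List smo_lms(NumericVector x, NumericVector rc, NumericVector rs,
             double mu, NumericVector w0) {
  const int n = x.size();
  double w1 = w0[0], w2 = w0[1];
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    double err = x[i] - (w1 * rc[i] + w2 * rs[i]);
    e[i] = err;
    w1 += 2.0 * mu * err * rc[i];
    w2 += 2.0 * mu * err * rs[i];
  }
  return List::create(_["e"] = e, _["w"] = NumericVector::create(w1, w2));
}
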