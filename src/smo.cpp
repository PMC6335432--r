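// Deterministic SMO solver for the soft-margin SVM dual with a precomputed
// Gram matrix (maximal-violating-pair working-set selection).
//
//   min_alpha 1/2 a' Q a - e' a,  Q_ij = y_i y_j K_ij,
//   s.t. y' a = 0, 0 <= a_i <= C.
//
// The pair update moves along alpha_i += y_i * t, alpha_j -= y_j * t, which
// preserves the equality constraint. Indefinite Gram matrices (sigmoid
// kernels) are handled by flooring the curvature term; convergence is then
// best-effort within max_iter and reported through the `converged` flag.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C, double tol = 1e-5,
               int max_iter = 200000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("Gram/label dimension mismatch");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;

  while (iter < max_iter) {
    iter++;
    // working-set selection: most violating pair
    int i = -1, j = -1;
    double gmax = -R_PosInf, gmin = R_PosInf;
    for (int k = 0; k < n; k++) {
      double v = -y[k] * G[k];
      bool up = (y[k] > 0 && alpha[k] < C) || (y[k] < 0 && alpha[k] > 0);
      bool low = (y[k] > 0 && alpha[k] > 0) || (y[k] < 0 && alpha[k] < C);
      if (up && v > gmax) { gmax = v; i = k; }
      if (low && v < gmin) { gmin = v; j = k; }
    }
    m_up = gmax;
    m_low = gmin;
    if (i < 0 || j < 0 || gmax - gmin < tol) {
      converged = true;
      break;
    }
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double tstar = (gmax - gmin) / quad;
    // box constraints on the step size t >= 0
    double tmax_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double tmax_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    double t = std::min(tstar, std::min(tmax_i, tmax_j));
    if (t <= 0) { converged = true; break; }
    alpha[i] += y[i] * t;
    alpha[j] -= y[j] * t;
    if (alpha[i] < 0) alpha[i] = 0;
    if (alpha[i] > C) alpha[i] = C;
    if (alpha[j] < 0) alpha[j] = 0;
    if (alpha[j] > C) alpha[j] = C;
    for (int k = 0; k < n; k++)
      G[k] += t * y[k] * (K(k, i) - K(k, j));
  }

  // bias: average -y_i G_i over free support vectors, else violation midpoint
  double bsum = 0.0;
  int bcount = 0;
  for (int k = 0; k < n; k++) {
    if (alpha[k] > 1e-10 && alpha[k] < C - 1e-10) {
      bsum += -y[k] * G[k];
      bcount++;
    }
  }
  double bias = (bcount > 0) ? bsum / bcount : 0.5 * (m_up + m_low);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = bias, _["iter"] = iter,
                      _["converged"] = converged);
}
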