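#include <Rcpp.h>
using namespace Rcpp;

// Deterministic SMO solver for the soft-margin SVM dual
//
//   min_a  1/2 a' Q a - e' a,   0 <= a_i <= C,  Q_ij = y_i y_j K_ij
//
// Working-set selection is second order (maximal violation for i, largest
// guaranteed objective decrease for j) with lowest-index tie-breaking, so
// the solver is bitwise reproducible: identical (K, y, C, eps) always
// yield identical (alpha, b).
//
// Convergence: m - M <= eps * max(1, C) where
//   m = max_{i in I_up} -y_i G_i,  M = min_{i in I_low} -y_i G_i.
// The tolerance is relative to C because the dual gradient scales with C;
// an absolute gap of eps at large C is numerically unreachable on
// non-separable data.

static const double TAU = 1e-12;

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double eps,
               double max_iter) {
  int n = y.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("kernel matrix dimensions do not match label vector");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0); // gradient of the dual at alpha = 0
  double tol = eps * std::max(1.0, C);

  double iter = 0.0;
  double m = 0.0, M = 0.0;
  for (;; iter += 1.0) {
    // i: maximal violation in I_up; M tracked for the stopping rule
    int i = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) M = v;
    }
    if (i < 0 || m - M <= tol) break;

    // j: second-order selection — largest guaranteed objective decrease
    int j = -1;
    double best = 0.0;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      double grad_diff = m + y[t] * G[t]; // m - (-y_t G_t)
      if (grad_diff > 0) {
        double a = K(i, i) + K(t, t) - 2.0 * K(i, t); // ||phi_i - phi_t||^2
        if (a <= 0) a = TAU;
        double dec = -(grad_diff * grad_diff) / a;
        if (dec < best) { best = dec; j = t; }
      }
    }
    if (j < 0) break;
    if (iter >= max_iter)
      stop("SMO did not converge within the iteration cap (%.0f)", max_iter);

    double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj - 2.0 * Kij; // Q_ii + Q_jj + 2 Q_ij with Q_ij = -K_ij
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break; // numerically stuck at the box
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias: average over free support vectors, else midpoint of the bounds
  double b, sum_yg = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) { sum_yg += -y[t] * G[t]; ++nfree; }
  }
  if (nfree > 0)
    b = sum_yg / nfree;
  else
    b = (m + M) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m - M);
}
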