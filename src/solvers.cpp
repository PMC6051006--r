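#include <Rcpp.h>
using namespace Rcpp;

// Majorization-minimization solver for 1-D total variation denoising,
//   argmin_x 1/2 ||y - x||^2 + lam * ||Dx||_1 ,  D = first-order difference.
// Each iteration solves the tridiagonal system
//   ( diag(|Dx_k| / lam) + D D^T ) z = D y,   x_{k+1} = y - D^T z,
// obtained from the quadratic majorizer of |.| at the current iterate
// (matrix-inversion-lemma form; D D^T is tridiag(-1, 2, -1)).
// Returns the iterate plus the objective trajectory (monotone by construction).
// [[Rcpp::export(name = ".tvd_mm_cpp")]]
List tvd_mm_cpp(NumericVector y, double lam, int n_iter, double tol) {
  const int n = y.size();
  const int m = n - 1;
  const double eps = 1e-10;
  NumericVector x = clone(y);
  std::vector<double> obj;
  obj.reserve(n_iter + 1);

  std::vector<double> dy(m), a(m), b(m), c(m), z(m), cp(m), dp(m);
  for (int i = 0; i < m; ++i) dy[i] = y[i + 1] - y[i];

  // objective at the current iterate
  auto objective = [&](const NumericVector& xx) {
    double fit = 0.0, tv = 0.0;
    for (int i = 0; i < n; ++i) { double r = y[i] - xx[i]; fit += r * r; }
    for (int i = 0; i < m; ++i) tv += std::fabs(xx[i + 1] - xx[i]);
    return 0.5 * fit + lam * tv;
  };

  double J_prev = objective(x);
  obj.push_back(J_prev);
  int iters = 0;

  if (lam <= 0.0 || m < 1) {
    return List::create(_["x"] = x, _["objective"] = wrap(obj),
                        _["iterations"] = 0);
  }

  for (int k = 0; k < n_iter; ++k) {
    // tridiagonal system: diag a = |Dx|/lam + 2, off-diagonals -1
    for (int i = 0; i < m; ++i) {
      double dx = x[i + 1] - x[i];
      double ad = std::fabs(dx);
      if (ad < eps) ad = eps;
      a[i] = ad / lam + 2.0;
      b[i] = -1.0;   // sub-diagonal
      c[i] = -1.0;   // super-diagonal
    }
    // Thomas algorithm
    cp[0] = c[0] / a[0];
    dp[0] = dy[0] / a[0];
    for (int i = 1; i < m; ++i) {
      double denom = a[i] - b[i] * cp[i - 1];
      cp[i] = c[i] / denom;
      dp[i] = (dy[i] - b[i] * dp[i - 1]) / denom;
    }
    z[m - 1] = dp[m - 1];
    for (int i = m - 2; i >= 0; --i) z[i] = dp[i] - cp[i] * z[i + 1];

    // x = y - D^T z
    x[0] = y[0] + z[0];
    for (int i = 1; i < m; ++i) x[i] = y[i] - (z[i - 1] - z[i]);
    x[n - 1] = y[n - 1] - z[m - 1];

    double J = objective(x);
    obj.push_back(J);
    iters = k + 1;
    if (J_prev > 0.0 && std::fabs(J_prev - J) <= tol * J_prev) break;
    J_prev = J;
  }

  return List::create(_["x"] = x, _["objective"] = wrap(obj),
                      _["iterations"] = iters);
}

// Dual coordinate descent for the L1-loss linear SVM
//   min_w 1/2 ||w||^2 + C sum_i max(0, 1 - y_i <w, x_i>),
// with the intercept absorbed as a constant trailing feature of X.
// Deterministic cyclic sweeps; stops when the largest projected-gradient
// violation in a sweep falls below tol.
// [[Rcpp::export(name = ".svm_dcd_cpp")]]
List svm_dcd_cpp(NumericMatrix X, NumericVector y, double C,
                 double tol, int max_passes) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d), alpha(n);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  int pass = 0;
  double max_pg = R_PosInf;
  for (pass = 0; pass < max_passes; ++pass) {
    max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double score = 0.0;
      for (int j = 0; j < d; ++j) score += w[j] * X(i, j);
      double G = y[i] * score - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  return List::create(_["w"] = w, _["alpha"] = alpha,
                      _["passes"] = pass + 1, _["max_violation"] = max_pg);
}
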