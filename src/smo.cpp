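#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin C-SVC dual solver: SMO with second-order working-set
// selection and periodic exact gradient refresh.  Minimizes
// 1/2 a'Qa - e'a with Q_ij = y_i y_j K_ij subject to 0 <= a_i <= C and
// y'a = 0.  Deterministic given inputs.
//
// K    : symmetric kernel (Gram) matrix, n x n
// y    : labels in {+1, -1}
// C    : box constraint
// tol  : KKT stopping tolerance on the maximal violating pair
// returns alpha, bias b (decision f(x) = sum_i alpha_i y_i K(x_i, x) + b),
// iterations and convergence flag.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-6, int max_iter = 10000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("dimension mismatch");
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0);
  // gradient of the dual objective: G_t = sum_s Q_ts alpha_s - 1
  std::vector<double> G(n, -1.0);
  std::vector<double> diag(n);
  for (int t = 0; t < n; ++t) diag[t] = K(t, t);

  int iter = 0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;
  double viol = std::numeric_limits<double>::infinity();
  double last_checkpoint_viol = std::numeric_limits<double>::infinity();
  bool stalled = false;
  const int refresh = 1 << 16;   // exact gradient recompute interval

  while (iter < max_iter) {
    if (iter > 0 && iter % refresh == 0) {
      // rebuild the gradient from alpha to remove accumulated drift
      std::vector<double> ay(n);
      for (int s = 0; s < n; ++s) ay[s] = alpha[s] * y[s];
      for (int t = 0; t < n; ++t) {
        const double *Kt = &K(0, t);
        double acc = 0.0;
        for (int s = 0; s < n; ++s) acc += Kt[s] * ay[s];
        G[t] = y[t] * acc - 1.0;
      }
      // stall detection: SMO can cycle above the target tolerance in
      // double precision; stop once checkpoints no longer improve
      if (viol > last_checkpoint_viol * 0.99) { stalled = true; }
      last_checkpoint_viol = viol;
    }

    // first-order choice of i in I_up
    int i = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      if (in_up && v > gmax) { gmax = v; i = t; }
    }
    if (i < 0) { converged = true; break; }
    const double *Ki = &K(0, i);

    // second-order choice of j among violating members of I_low
    int j = -1;
    double obj_min = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      if (v < gmin) gmin = v;
      double b_it = gmax - v;
      if (b_it > 0) {
        double a_it = diag[i] + diag[t] - 2.0 * Ki[t];
        if (a_it <= 0) a_it = TAU;
        double obj = -(b_it * b_it) / a_it;
        if (obj < obj_min) { obj_min = obj; j = t; }
      }
    }
    m_up = gmax; m_low = gmin;
    viol = gmax - gmin;
    if (viol < tol || j < 0) { converged = true; break; }
    if (stalled) { converged = true; break; }

    const double *Kj = &K(0, j);
    double quad = diag[i] + diag[j] - 2.0 * Ki[j];
    if (quad <= 0) quad = TAU;
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
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

    double di = y[i] * (alpha[i] - ai_old);
    double dj = y[j] * (alpha[j] - aj_old);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (Ki[t] * di + Kj[t] * dj);
    ++iter;
  }

  // bias: average of -y G over free support vectors, else midpoint of the
  // feasibility interval
  double b = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) b /= nfree; else b = (m_up + m_low) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["violation"] = (viol == std::numeric_limits<double>::infinity()) ? 0.0 : viol);
}
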