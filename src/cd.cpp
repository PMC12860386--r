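#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional penalized updates for coordinate descent.
// z is the partial-residual inner product (1/n) x_j' r + v_j * beta_j,
// v the column curvature (1/n) x_j' x_j, l1 = alpha*lambda*pf_j the
// absolute-value penalty, l2 = (1-alpha)*lambda*pf_j the ridge penalty.
// Rotated columns are not unit-scale, so v enters every denominator.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static inline double mcp_pen(double b, double l1, double gamma) {
  b = std::fabs(b);
  if (b <= gamma * l1) return l1 * b - b * b / (2.0 * gamma);
  return 0.5 * gamma * l1 * l1;
}

static inline double scad_pen(double b, double l1, double gamma) {
  b = std::fabs(b);
  if (b <= l1) return l1 * b;
  if (b <= gamma * l1)
    return (2.0 * gamma * l1 * b - b * b - l1 * l1) / (2.0 * (gamma - 1.0));
  return l1 * l1 * (gamma + 1.0) / 2.0;
}

// family: 0 lasso, 1 MCP, 2 SCAD (each with optional ridge component l2)
static double update_one(double z, double v, double l1, double l2,
                         double gamma, int family) {
  double den = v + l2;
  if (family == 0 || l1 == 0.0) {
    if (l1 == 0.0 && l2 == 0.0) return z / v;  // unpenalized column
    return soft(z, l1) / den;
  }
  if (family == 1) {  // MCP firm rule
    if (std::fabs(z) <= gamma * l1 * den) {
      double den_firm = den - 1.0 / gamma;
      if (den_firm > 1e-12) return soft(z, l1) / den_firm;
      // non-convex edge (small curvature): compare endpoints by objective
      double b1 = z / den;
      double f1 = 0.5 * den * b1 * b1 - z * b1 + mcp_pen(b1, l1, gamma);
      return (f1 < 0.0) ? b1 : 0.0;
    }
    return z / den;
  }
  // SCAD three-piece rule
  double az = std::fabs(z);
  if (az <= l1 * (den + 1.0)) return soft(z, l1) / den;
  if (az <= gamma * l1 * den) {
    double den2 = den - 1.0 / (gamma - 1.0);
    if (den2 > 1e-12) return soft(z, gamma * l1 / (gamma - 1.0)) / den2;
    double b1 = z / den;
    double f1 = 0.5 * den * b1 * b1 - z * b1 + scad_pen(b1, l1, gamma);
    return (f1 < 0.0) ? b1 : 0.0;
  }
  return z / den;
}

static double penalty_value(const NumericVector& beta,
                            const NumericVector& pf, double lambda,
                            double alpha, double gamma, int family) {
  double s = 0.0;
  for (int j = 0; j < beta.size(); ++j) {
    double l1 = alpha * lambda * pf[j];
    double l2 = (1.0 - alpha) * lambda * pf[j];
    double b = beta[j];
    if (family == 0) s += l1 * std::fabs(b);
    else if (family == 1) s += mcp_pen(b, l1, gamma);
    else s += scad_pen(b, l1, gamma);
    s += 0.5 * l2 * b * b;
  }
  return s;
}

// Sweep over the columns listed in idx; returns max |delta beta_j| sqrt(v_j).
static double sweep_set(const NumericMatrix& X, NumericVector& r,
                        NumericVector& beta, const NumericVector& v,
                        const NumericVector& pf, const IntegerVector& idx,
                        double lambda, double alpha, double gamma,
                        int family, int n) {
  double maxdiff = 0.0;
  for (int t = 0; t < idx.size(); ++t) {
    int j = idx[t];
    if (v[j] <= 1e-300) continue;  // degenerate column: leave at 0
    const double* xj = &X(0, j);
    double zin = 0.0;
    for (int i = 0; i < n; ++i) zin += xj[i] * r[i];
    double z = zin / n + v[j] * beta[j];
    double l1 = alpha * lambda * pf[j];
    double l2 = (1.0 - alpha) * lambda * pf[j];
    double bnew = update_one(z, v[j], l1, l2, gamma, family);
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      beta[j] = bnew;
      double chg = std::fabs(d) * std::sqrt(v[j]);
      if (chg > maxdiff) maxdiff = chg;
    }
  }
  return maxdiff;
}

// Coordinate descent at a single lambda over the supplied candidate columns.
// X holds the candidate columns (n x m); r is the current full residual
// y_tilde - X_all beta_all (columns outside the candidate set all have
// beta = 0). Active-set strategy: iterate on the currently nonzero /
// unpenalized columns until converged, then one full sweep over all m
// columns; repeat until the full sweep changes nothing beyond tolerance.
// Convergence: max_j |delta beta_j| sqrt(v_j) < tol * y_scale.
// [[Rcpp::export]]
List cd_solve(NumericMatrix X, NumericVector r_in, NumericVector beta_in,
              NumericVector v, NumericVector pf, double lambda,
              double alpha, double gamma, int family, double tol,
              int max_iter, double y_scale, bool track_objective) {
  int n = X.nrow(), m = X.ncol();
  NumericVector r = clone(r_in), beta = clone(beta_in);
  double thresh = tol * std::max(y_scale, 1e-12);
  int sweeps = 0;
  bool converged = false;
  std::vector<double> obj_trace;

  IntegerVector all_idx(m);
  for (int j = 0; j < m; ++j) all_idx[j] = j;

  auto record_obj = [&]() {
    if (!track_objective) return;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    obj_trace.push_back(rss / (2.0 * n) +
                        penalty_value(beta, pf, lambda, alpha, gamma, family));
  };

  record_obj();
  while (sweeps < max_iter) {
    double d_full = sweep_set(X, r, beta, v, pf, all_idx, lambda, alpha,
                              gamma, family, n);
    ++sweeps;
    record_obj();
    if (d_full < thresh) { converged = true; break; }
    // inner iterations on the active set
    while (sweeps < max_iter) {
      std::vector<int> act;
      for (int j = 0; j < m; ++j)
        if (beta[j] != 0.0 || pf[j] == 0.0) act.push_back(j);
      IntegerVector act_idx(act.begin(), act.end());
      double d_act = sweep_set(X, r, beta, v, pf, act_idx, lambda, alpha,
                               gamma, family, n);
      ++sweeps;
      record_obj();
      if (d_act < thresh) break;
    }
  }

  return List::create(_["beta"] = beta, _["r"] = r, _["iter"] = sweeps,
                      _["converged"] = converged,
                      _["objective"] = wrap(obj_trace));
}
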