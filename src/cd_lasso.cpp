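#include <Rcpp.h>
using namespace Rcpp;

// Cyclical coordinate descent for
//   (1/2n) ||y - W b||^2 + lambda * sum_j pf_j |b_j|
// over a decreasing lambda sequence with warm starts.
//
// W holds unpenalized columns (pf = 0, e.g. Sex/Age/Smoke) and penalized
// SNP columns (pf = 1) side by side.  Columns need not have unit norm:
// the update uses the exact per-column scale v_j = ||w_j||^2 / n, so the
// same routine serves full-data fits, CV fold fits on row subsets, and
// bootstrap refits.  Columns with v_j ~ 0 (monomorphic in the rows seen)
// are pinned to zero.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cd_lasso_path_cpp(const NumericMatrix& W,
                       const NumericVector& y,
                       const NumericVector& penalty_factor,
                       const NumericVector& lambdas,
                       double tol,
                       int max_iter,
                       bool track_objective,
                       Nullable<NumericVector> beta_init = R_NilValue) {
  const int n = W.nrow(), m = W.ncol(), L = lambdas.size();
  const double ninv = 1.0 / n;

  std::vector<double> v(m);          // ||w_j||^2 / n
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* wj = &W(0, j);
    for (int i = 0; i < n; ++i) s += wj[i] * wj[i];
    v[j] = s * ninv;
  }

  std::vector<double> beta(m, 0.0);
  std::vector<double> r(y.begin(), y.end());
  if (beta_init.isNotNull()) {
    NumericVector b0(beta_init);
    if (b0.size() != m) stop("beta_init has wrong length");
    for (int j = 0; j < m; ++j) {
      beta[j] = (v[j] > 1e-12) ? b0[j] : 0.0;
      if (beta[j] != 0.0) {
        const double* wj = &W(0, j);
        for (int i = 0; i < n; ++i) r[i] -= wj[i] * beta[j];
      }
    }
  }

  NumericMatrix coefs(m, L);
  IntegerVector n_sweeps(L);
  LogicalVector converged(L);
  NumericVector objective(L);
  List traces(track_objective ? L : 0);

  auto obj_value = [&](double lambda) {
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    double pen = 0.0;
    for (int j = 0; j < m; ++j) pen += penalty_factor[j] * std::fabs(beta[j]);
    return 0.5 * rss * ninv + lambda * pen;
  };

  // one coordinate sweep over `idx`; returns max absolute coefficient change
  auto sweep = [&](const std::vector<int>& idx, double lambda) {
    double dmax = 0.0;
    for (int j : idx) {
      if (v[j] <= 1e-12) continue;
      const double* wj = &W(0, j);
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += wj[i] * r[i];
      g *= ninv;
      double z = g + v[j] * beta[j];
      double bnew = soft(z, lambda * penalty_factor[j]) / v[j];
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= wj[i] * d;
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > dmax) dmax = ad;
      }
    }
    return dmax;
  };

  std::vector<int> all(m);
  for (int j = 0; j < m; ++j) all[j] = j;

  for (int l = 0; l < L; ++l) {
    const double lambda = lambdas[l];
    int iters = 0;
    bool ok = false;
    std::vector<double> trace;

    while (iters < max_iter) {
      double dmax = sweep(all, lambda);
      ++iters;
      if (track_objective) trace.push_back(obj_value(lambda));
      if (dmax < tol) { ok = true; break; }
      // active-set refinement: iterate over current support until stable
      std::vector<int> active;
      active.reserve(64);
      for (int j = 0; j < m; ++j)
        if (beta[j] != 0.0 || penalty_factor[j] == 0.0) active.push_back(j);
      while (iters < max_iter) {
        double da = sweep(active, lambda);
        ++iters;
        if (track_objective) trace.push_back(obj_value(lambda));
        if (da < tol) break;
      }
    }

    for (int j = 0; j < m; ++j) coefs(j, l) = beta[j];
    n_sweeps[l] = iters;
    converged[l] = ok;
    objective[l] = obj_value(lambda);
    if (track_objective) traces[l] = NumericVector(trace.begin(), trace.end());
  }

  List out = List::create(_["coefs"] = coefs,
                          _["n_sweeps"] = n_sweeps,
                          _["converged"] = converged,
                          _["objective"] = objective);
  if (track_objective) out["objective_trace"] = traces;
  return out;
}
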