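#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method.  Propensities are mass-action falling
// factorials; the networks handled here are first-order, but the
// kernel supports general integer educt stoichiometry.  Randomness
// comes from R's RNG so set.seed() gives full reproducibility.

static double propensity(const IntegerMatrix& Q, const NumericVector& k,
                         const IntegerVector& x, int i) {
  double a = k[i];
  for (int j = 0; j < Q.nrow(); ++j) {
    int q = Q(j, i);
    if (q == 0) continue;
    if (x[j] < q) return 0.0;
    for (int r = 0; r < q; ++r) a *= (x[j] - r);
  }
  return a;
}

// [[Rcpp::export]]
List ssa_trajectory_cpp(IntegerMatrix Q, IntegerMatrix R, NumericVector k,
                        IntegerVector x0, double t_end,
                        int max_events = 10000000) {
  int n = Q.nrow(), m = Q.ncol();
  IntegerVector x = clone(x0);
  std::vector<double> times;
  std::vector<int> states;
  double t = 0.0;
  times.push_back(0.0);
  for (int j = 0; j < n; ++j) states.push_back(x[j]);
  int ev = 0;
  while (t < t_end) {
    double a0 = 0.0;
    std::vector<double> a(m);
    for (int i = 0; i < m; ++i) { a[i] = propensity(Q, k, x, i); a0 += a[i]; }
    if (a0 <= 0.0) break;
    double tau = R::exp_rand() / a0;
    if (t + tau > t_end) break;
    t += tau;
    double u = unif_rand() * a0, acc = 0.0;
    int ri = m - 1;
    for (int i = 0; i < m; ++i) { acc += a[i]; if (u <= acc) { ri = i; break; } }
    for (int j = 0; j < n; ++j) x[j] += R(j, ri) - Q(j, ri);
    times.push_back(t);
    for (int j = 0; j < n; ++j) states.push_back(x[j]);
    if (++ev >= max_events) stop("maximum event count exceeded");
  }
  IntegerMatrix S(times.size(), n);
  for (size_t r = 0; r < times.size(); ++r)
    for (int j = 0; j < n; ++j) S(r, j) = states[r * n + j];
  return List::create(_["times"] = wrap(times), _["states"] = S);
}

// [[Rcpp::export]]
IntegerMatrix ssa_endstates_cpp(IntegerMatrix Q, IntegerMatrix R,
                                NumericVector k, IntegerMatrix x0,
                                double t_end, int max_events = 10000000) {
  int n = Q.nrow(), m = Q.ncol(), runs = x0.nrow();
  IntegerMatrix out(runs, n);
  IntegerVector x(n);
  for (int run = 0; run < runs; ++run) {
    for (int j = 0; j < n; ++j) x[j] = x0(run, j);
    double t = 0.0;
    int ev = 0;
    while (t < t_end) {
      double a0 = 0.0;
      double a[64];
      if (m > 64) stop("at most 64 reactions supported");
      for (int i = 0; i < m; ++i) { a[i] = propensity(Q, k, x, i); a0 += a[i]; }
      if (a0 <= 0.0) break;
      double tau = R::exp_rand() / a0;
      if (t + tau > t_end) break;
      t += tau;
      double u = unif_rand() * a0, acc = 0.0;
      int ri = m - 1;
      for (int i = 0; i < m; ++i) { acc += a[i]; if (u <= acc) { ri = i; break; } }
      for (int j = 0; j < n; ++j) x[j] += R(j, ri) - Q(j, ri);
      if (++ev >= max_events) stop("maximum event count exceeded");
    }
    for (int j = 0; j < n; ++j) out(run, j) = x[j];
    if (run % 4096 == 0) checkUserInterrupt();
  }
  return out;
}
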