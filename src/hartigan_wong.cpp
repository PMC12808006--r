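#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance between row i of X and row c of C.
static inline double row_dist2(const NumericMatrix &X, int i,
                               const NumericMatrix &C, int c) {
  const int p = X.ncol();
  double d = 0.0;
  for (int j = 0; j < p; ++j) {
    const double diff = X(i, j) - C(c, j);
    d += diff * diff;
  }
  return d;
}

// Hartigan-Wong k-means: points move individually between clusters when the
// size-adjusted transfer gain n_t*d2(x,c_t)/(n_t+1) undercuts the removal
// cost n_s*d2(x,c_s)/(n_s-1). Centroids are updated incrementally after each
// transfer, so every accepted move strictly decreases the total WCSS
// (descent property). Ties in the initial Voronoi assignment and in the
// target search resolve to the lower cluster index; singletons never move,
// so clusters cannot empty during iteration.
// [[Rcpp::export]]
List hw_core(NumericMatrix X, NumericMatrix init, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), k = init.nrow();
  NumericMatrix C(clone(init));
  IntegerVector assign(n);
  IntegerVector count(k);

  // Initial Voronoi partition of the starting centroids.
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bd = row_dist2(X, i, C, 0);
    for (int c = 1; c < k; ++c) {
      const double d = row_dist2(X, i, C, c);
      if (d < bd) { bd = d; best = c; }
    }
    assign[i] = best;
    count[best]++;
  }

  // Empty clusters inherit the point currently farthest from its own
  // centroid (taken only from clusters that can spare one).
  for (int c = 0; c < k; ++c) {
    if (count[c] > 0) continue;
    int far_i = -1;
    double far_d = -1.0;
    for (int i = 0; i < n; ++i) {
      if (count[assign[i]] < 2) continue;
      const double d = row_dist2(X, i, C, assign[i]);
      if (d > far_d) { far_d = d; far_i = i; }
    }
    if (far_i < 0) stop("cannot repair empty cluster: too few distinct points");
    count[assign[far_i]]--;
    assign[far_i] = c;
    count[c] = 1;
  }

  // Exact centroids of the repaired partition.
  std::fill(C.begin(), C.end(), 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) C(assign[i], j) += X(i, j);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j) C(c, j) /= count[c];

  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    int transfers = 0;
    for (int i = 0; i < n; ++i) {
      const int s = assign[i];
      if (count[s] < 2) continue;
      const double d2s = row_dist2(X, i, C, s);
      const double removal = count[s] * d2s / (count[s] - 1.0);
      int best_t = -1;
      double best_gain = R_PosInf;
      for (int t = 0; t < k; ++t) {
        if (t == s) continue;
        const double g = count[t] * row_dist2(X, i, C, t) / (count[t] + 1.0);
        if (g < best_gain) { best_gain = g; best_t = t; }
      }
      // Guard against float-noise cycling: require a strictly positive gain.
      if (best_t >= 0 && best_gain < removal * (1.0 - 1e-12)) {
        const int ns = count[s], nt = count[best_t];
        for (int j = 0; j < p; ++j) {
          C(s, j) = (C(s, j) * ns - X(i, j)) / (ns - 1.0);
          C(best_t, j) = (C(best_t, j) * nt + X(i, j)) / (nt + 1.0);
        }
        count[s]--;
        count[best_t]++;
        assign[i] = best_t;
        ++transfers;
      }
    }
    if (transfers == 0) { converged = true; break; }
  }

  // Remove incremental round-off: recompute centroids and WCSS exactly.
  std::fill(C.begin(), C.end(), 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) C(assign[i], j) += X(i, j);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j) C(c, j) /= count[c];
  double wcss = 0.0;
  for (int i = 0; i < n; ++i) wcss += row_dist2(X, i, C, assign[i]);

  return List::create(_["assignments"] = assign + 1,
                      _["centroids"] = C,
                      _["wcss"] = wcss,
                      _["converged"] = converged,
                      _["n_iter"] = iter,
                      _["sizes"] = count);
}
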