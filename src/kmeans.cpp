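#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Nearest-centre assignment for Lloyd iterations: returns 1-based cluster
// index and squared distance to the winning centre for every point.
// A previous assignment (0 = none) warm-starts the best distance so the
// partial-sum early exit prunes most centres after a few dimensions.
// [[Rcpp::export(name = ".kmeans_assign_cpp")]]
List kmeans_assign_cpp(NumericMatrix x, NumericMatrix centers,
                       IntegerVector prev) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  const bool warm = prev.size() == n;
  // row-major copies for cache-friendly inner loops
  std::vector<double> xr((size_t)n * d), cr((size_t)k * d);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < d; ++t) xr[(size_t)i * d + t] = x(i, t);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < d; ++t) cr[(size_t)j * d + t] = centers(j, t);

  IntegerVector assign(n);
  NumericVector d2best(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * d];
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    if (warm && prev[i] >= 1 && prev[i] <= k) {
      bj = prev[i] - 1;
      const double* cj = &cr[(size_t)bj * d];
      best = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = xi[t] - cj[t];
        best += diff * diff;
      }
    }
    for (int j = 0; j < k; ++j) {
      if (warm && j == bj) continue;
      const double* cj = &cr[(size_t)j * d];
      double s = 0.0;
      int t = 0;
      for (; t + 1 < d; t += 2) {
        const double a = xi[t] - cj[t];
        const double b = xi[t + 1] - cj[t + 1];
        s += a * a + b * b;
        if (s >= best) break;
      }
      if (s >= best) continue;
      if (t < d) {
        const double a = xi[t] - cj[t];
        s += a * a;
      }
      if (s < best) { best = s; bj = j; }
    }
    assign[i] = bj + 1;
    d2best[i] = best;
  }
  return List::create(_["assignment"] = assign, _["d2"] = d2best);
}

// Squared Euclidean distance from every row of x to a single point.
// [[Rcpp::export(name = ".dist2_point_cpp")]]
NumericVector dist2_point_cpp(NumericMatrix x, NumericVector c) {
  const int n = x.nrow(), d = x.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < d; ++t) {
      const double diff = x(i, t) - c[t];
      s += diff * diff;
    }
    out[i] = s;
  }
  return out;
}
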