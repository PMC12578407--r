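#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Count permutations of y whose |Pearson r| with x reaches the observed |r|.
// Uses R's RNG (Fisher-Yates with unif_rand), so results respect set.seed()
// and are reproducible across platforms. x and y are compared through dot
// products of the centered/scaled vectors, which is a monotone transform of r.
//' @noRd
// [[Rcpp::export]]
int cpp_perm_corr_count(NumericVector x, NumericVector y, int n_perm) {
  const int n = x.size();
  std::vector<double> xs(n), ys(n);
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) {
    xs[i] = x[i] - mx; ys[i] = y[i] - my;
    sx += xs[i] * xs[i]; sy += ys[i] * ys[i];
  }
  if (sx <= 0 || sy <= 0) stop("constant vector: correlation undefined");
  sx = std::sqrt(sx); sy = std::sqrt(sy);
  for (int i = 0; i < n; ++i) { xs[i] /= sx; ys[i] /= sy; }

  double dot_obs = 0;
  for (int i = 0; i < n; ++i) dot_obs += xs[i] * ys[i];
  const double thr = std::fabs(dot_obs) - 1e-9;

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double dot = 0;
    for (int i = 0; i < n; ++i) dot += xs[i] * ys[perm[i]];
    if (std::fabs(dot) >= thr) ++count;
  }
  return count;
}
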