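#include <Rcpp.h>
using namespace Rcpp;

// Pairwise sums over unordered pairs i < j of unit vectors:
// out[0] = sum acos(u_i . u_j), out[1] = sum sin(acos(u_i . u_j)).
// Dot products are clamped to [-1, 1] before acos to absorb rounding in
// numerically (anti)parallel pairs.
// [[Rcpp::export]]
NumericVector gine_pair_sums(NumericMatrix U) {
  const int n = U.nrow();
  const double *x = &U(0, 0), *y = &U(0, 1), *z = &U(0, 2);
  double sum_theta = 0.0, sum_sin = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      double d = xi * x[j] + yi * y[j] + zi * z[j];
      if (d > 1.0) d = 1.0; else if (d < -1.0) d = -1.0;
      sum_theta += std::acos(d);
      sum_sin += std::sqrt(1.0 - d * d);
    }
  }
  return NumericVector::create(sum_theta, sum_sin);
}
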