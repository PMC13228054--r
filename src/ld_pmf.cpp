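#include <Rcpp.h>
using namespace Rcpp;

// Lea-Coulson (Luria-Delbruck, relative mutant fitness 1, full plating)
// probability mass function by the compound-Poisson recursion.
//
// Clone-size law: P(J = j) = 1/(j(j+1)), j >= 1, so j*P(J=j) = 1/(j+1) and
//   p_0 = exp(-m),   p_n = (m/n) * sum_{j=1..n} p_{n-j} / (j + 1).
//
// O(n_max^2); kept in C++ because the recursion sits inside the ML
// optimizer's inner loop with n_max up to the jackpot cap (1e4).
// [[Rcpp::export]]
NumericVector ld_pmf_cpp(double m, int n_max) {
  if (m < 0) stop("m must be non-negative");
  if (n_max < 0) stop("n_max must be non-negative");
  NumericVector p(n_max + 1);
  p[0] = std::exp(-m);
  for (int n = 1; n <= n_max; ++n) {
    double s = 0.0;
    for (int j = 1; j <= n; ++j) s += p[n - j] / (double)(j + 1);
    p[n] = m * s / (double)n;
  }
  return p;
}
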