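#include <Rcpp.h>
using namespace Rcpp;

// Single-chain Gibbs sampler for the conditional-Gaussian pairwise model.
//
// Each sweep updates every node in order from its full conditional
//   x_i | x_-i  ~  N(intercept_i + sum_j W(i,j) x_j, sigma^2).
// The chain runs `burn_in` sweeps under the level-0 weights W0, then for each
// of the n retained states runs `thinning` sweeps under that draw's weight
// matrix (W1 when moderator[k] == 1, else W0) before recording. Uses R's RNG,
// so results are reproducible under set.seed().
//
// [[Rcpp::export]]
NumericMatrix gibbs_chain_cpp(NumericMatrix W0, NumericMatrix W1,
                              NumericVector intercepts, double sigma,
                              NumericVector x0, IntegerVector moderator,
                              int burn_in, int thinning) {
  const int p = intercepts.size();
  const int n = moderator.size();
  NumericVector x = clone(x0);
  NumericMatrix out(n, p);

  for (int s = 0; s < burn_in; ++s) {
    for (int i = 0; i < p; ++i) {
      double m = intercepts[i];
      for (int j = 0; j < p; ++j) m += W0(i, j) * x[j];
      x[i] = R::rnorm(m, sigma);
    }
  }

  for (int k = 0; k < n; ++k) {
    NumericMatrix W = (moderator[k] == 1) ? W1 : W0;
    for (int s = 0; s < thinning; ++s) {
      for (int i = 0; i < p; ++i) {
        double m = intercepts[i];
        for (int j = 0; j < p; ++j) m += W(i, j) * x[j];
        x[i] = R::rnorm(m, sigma);
      }
    }
    out(k, _) = x;
  }
  return out;
}
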