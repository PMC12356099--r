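#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for an HMM with diagonal-Gaussian emissions.
// X: n x F observations; mu: K x F state means; sd: K x F per-state
// standard deviations; logtrans: K x K log transition matrix; loginit: K
// log initial probabilities. Emission log-likelihoods are computed on the
// fly to keep memory at O(nK) for the backpointers only.
// [[Rcpp::export(name = ".viterbi_gauss_cpp")]]
List viterbi_gauss_cpp(NumericMatrix X, NumericMatrix mu, NumericMatrix sd,
                       NumericMatrix logtrans, NumericVector loginit) {
  const int n = X.nrow(), F = X.ncol(), K = mu.nrow();
  if (mu.ncol() != F || sd.nrow() != K || sd.ncol() != F ||
      logtrans.nrow() != K || logtrans.ncol() != K || loginit.size() != K)
    stop("dimension mismatch between observations and HMM parameters");
  std::vector<double> norm(K * F);
  std::vector<double> lognorm(K, 0.0);
  for (int k = 0; k < K; ++k) {
    for (int f = 0; f < F; ++f) {
      double s = sd(k, f);
      if (s <= 0) stop("observation standard deviations must be positive");
      norm[k * F + f] = 1.0 / (2.0 * s * s);
      lognorm[k] += -0.5 * std::log(2.0 * M_PI) - std::log(s);
    }
  }
  IntegerMatrix back(n, K);
  std::vector<double> prev(K), cur(K);
  auto emit = [&](int t, int k) {
    double ll = lognorm[k];
    for (int f = 0; f < F; ++f) {
      double d = X(t, f) - mu(k, f);
      ll -= d * d * norm[k * F + f];
    }
    return ll;
  };
  for (int k = 0; k < K; ++k) prev[k] = loginit[k] + emit(0, k);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = prev[j] + logtrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      back(t, k) = arg;
      cur[k] = best + emit(t, k);
    }
    std::swap(prev, cur);
  }
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (prev[k] > best) { best = prev[k]; arg = k; }
  if (!R_finite(best))
    stop("Viterbi decode failed: all paths have zero probability");
  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < n; ++t) path[t] += 1;  // 1-based for R
  return List::create(_["path"] = path, _["logp"] = best);
}
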