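#include <Rcpp.h>
using namespace Rcpp;

// Null SUMSTAT distribution: nDraws uniform without-replacement subsets of
// size k from the statistic universe, each summed. Subsets are drawn by a
// partial Fisher-Yates shuffle driven by R's RNG (so set.seed() makes the
// draws reproducible); leaving the index array permuted between draws does
// not disturb uniformity since every draw applies fresh random swaps.

// [[Rcpp::export]]
NumericVector null_sumstats(NumericVector stats, int k, int nDraws) {
  const int m = stats.size();
  if (k <= 0 || k > m) stop("set size must be in 1..universe size");
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  NumericVector out(nDraws);
  for (int d = 0; d < nDraws; ++d) {
    double s = 0.0;
    for (int i = 0; i < k; ++i) {
      int j = i + static_cast<int>(unif_rand() * (m - i));
      if (j >= m) j = m - 1;  // guard against unif_rand() == 1.0
      std::swap(idx[i], idx[j]);
      s += stats[idx[i]];
    }
    out[d] = s;
  }
  return out;
}
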