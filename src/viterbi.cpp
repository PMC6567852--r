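#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for an aggregated hidden Markov model with per-sample
// emission log densities. Ties in the back-pointers are broken toward the
// lower class index (lower conductance), so decoding is deterministic.
//
// logemis: n x K matrix of emission log densities.
// logtrans: K x K matrix of log transition probabilities.
// loginit:  length-K vector of log initial probabilities.
// Returns the 1-based maximum-likelihood class path.
// [[Rcpp::export(name = ".viterbi_decode")]]
IntegerVector viterbi_decode(NumericMatrix logemis, NumericMatrix logtrans,
                             NumericVector loginit) {
  const int n = logemis.nrow(), K = logemis.ncol();
  if (n == 0) stop("empty emission matrix");
  if (logtrans.nrow() != K || logtrans.ncol() != K || loginit.size() != K)
    stop("dimension mismatch between emissions, transitions and initial vector");

  IntegerMatrix back(n, K);
  std::vector<double> prev(K), cur(K);
  for (int k = 0; k < K; ++k) prev[k] = loginit[k] + logemis(0, k);

  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = prev[j] + logtrans(j, k);
        if (v > best) {  // strict >: ties keep the lower class index
          best = v;
          arg = j;
        }
      }
      cur[k] = best + logemis(t, k);
      back(t, k) = arg;
    }
    prev = cur;
  }

  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    if (prev[k] > best) {
      best = prev[k];
      arg = k;
    }
  }

  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < n; ++t) path[t] += 1;
  return path;
}
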