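#include <Rcpp.h>
using namespace Rcpp;

// Raw log-odds score of every window of a pre-encoded sequence under a PWM.
//
// seq: integer codes 1=A, 2=C, 3=G, 4=T, 5=N; logodds: 5 x W matrix whose
// fifth row is zero (N contributes nothing). Accumulates in long double so
// scores are bit-identical to R's sum() over the per-position contributions.
// [[Rcpp::export]]
NumericVector pwm_window_scores(const IntegerVector& seq,
                                const NumericMatrix& logodds) {
  const int W = logodds.ncol();
  const int L = seq.size();
  const int n = L - W + 1;
  if (n < 1) return NumericVector(0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    long double s = 0.0L;
    for (int j = 0; j < W; ++j) {
      s += logodds(seq[i + j] - 1, j);
    }
    out[i] = (double) s;
  }
  return out;
}
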