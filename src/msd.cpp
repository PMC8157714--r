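#include <Rcpp.h>
using namespace Rcpp;

// Time-averaged mean squared displacement over sliding origins.  Origins are
// strided so that at most `max_origins` are used per lag, keeping the cost
// bounded for long trajectories.
// [[Rcpp::export]]
NumericVector msd_cpp(NumericMatrix X, IntegerVector lags, int max_origins) {
  const int T = X.nrow();
  const int nl = lags.size();
  NumericVector out(nl);
  for (int li = 0; li < nl; ++li) {
    int L = lags[li];
    if (L <= 0 || L >= T) { out[li] = NA_REAL; continue; }
    int n_or = T - L;
    int stride = n_or > max_origins ? n_or / max_origins : 1;
    double acc = 0.0;
    long long cnt = 0;
    for (int t0 = 0; t0 < n_or; t0 += stride) {
      double s = 0.0;
      for (int a = 0; a < 3; ++a) {
        double d = X(t0 + L, a) - X(t0, a);
        s += d * d;
      }
      acc += s;
      ++cnt;
    }
    out[li] = acc / (double)cnt;
  }
  return out;
}
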