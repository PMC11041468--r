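#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Trailing median over the past `window` samples, restricted to samples
// whose quality flag is acceptable. An empty window holds the previous
// output (NA before any output exists). Even counts average the two middle
// values. O(n * w log w); w is at most a minute of samples here.
// [[Rcpp::export]]
Rcpp::NumericVector masked_running_median(Rcpp::NumericVector x,
                                          Rcpp::LogicalVector ok,
                                          int window) {
  const int n = x.size();
  if (window < 1) Rcpp::stop("window must be >= 1");
  Rcpp::NumericVector out(n);
  double prev = NA_REAL;
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    const int lo = std::max(0, i - window + 1);
    for (int k = lo; k <= i; ++k) {
      if (ok[k] == TRUE && Rcpp::NumericVector::is_na(x[k]) == false) {
        buf.push_back(x[k]);
      }
    }
    if (buf.empty()) {
      out[i] = prev;
    } else {
      std::sort(buf.begin(), buf.end());
      const size_t m = buf.size();
      out[i] = (m % 2 == 1) ? buf[m / 2]
                            : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
      prev = out[i];
    }
  }
  return out;
}
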