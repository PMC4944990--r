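#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <vector>

using namespace Rcpp;

// Sequential artifact filter for interbeat-interval series.
// An interval is accepted when it lies inside [band_lo, band_hi] and,
// once at least min_history intervals have been accepted, deviates no
// more than max_rel_dev from the median of the previous (up to `history`)
// accepted intervals. Rejected intervals are dropped, never interpolated.
// [[Rcpp::export(name = ".filter_nn_accept")]]
LogicalVector filter_nn_accept(NumericVector x, double band_lo,
                               double band_hi, double max_rel_dev,
                               int history, int min_history) {
  int n = x.size();
  LogicalVector accept(n);
  std::deque<double> buf;          // last `history` accepted, in time order
  std::vector<double> tmp;
  tmp.reserve(history);
  for (int k = 0; k < n; ++k) {
    double v = x[k];
    bool ok = (v >= band_lo && v <= band_hi);
    if (ok && (int)buf.size() >= min_history) {
      tmp.assign(buf.begin(), buf.end());
      int m = tmp.size();
      std::nth_element(tmp.begin(), tmp.begin() + m / 2, tmp.end());
      double med = tmp[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(tmp.begin(), tmp.begin() + m / 2);
        med = (med + lo) / 2.0;
      }
      ok = std::abs(v - med) <= max_rel_dev * med;
    }
    accept[k] = ok;
    if (ok) {
      buf.push_back(v);
      if ((int)buf.size() > history) buf.pop_front();
    }
  }
  return accept;
}
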