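#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median and quartile deviation of a sorted buffer (type-7 quantiles).
static double quantile7(const std::vector<double>& s, double p) {
  const int n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < n ? lo + 1 : lo;
  return s[lo] + (h - lo) * (s[hi] - s[lo]);
}

//' Rolling median and quartile deviation of the neighborhood excluding self
//'
//' For each index i the statistics are computed over the `width`-wide window
//' centered on i (shifted inward at the series ends so the window always holds
//' `width` observations) with observation i itself removed. Used by the
//' robust beat-artifact criterion.
//'
//' @param x numeric vector
//' @param width odd window width, `5 <= width <= length(x)`
//' @return matrix with columns `med` and `qd` (= (Q3 - Q1) / 2)
//' @keywords internal
// [[Rcpp::export(name = ".rollingMedQd")]]
NumericMatrix rolling_med_qd(NumericVector x, int width) {
  const int n = x.size();
  if (width < 5 || width % 2 == 0)
    stop("width must be odd and >= 5");
  if (n < width)
    stop("series shorter than window");
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("med", "qd");
  const int half = width / 2;
  std::vector<double> buf;
  buf.reserve(width);
  int cur_lo = -1;
  for (int i = 0; i < n; ++i) {
    int lo = i - half;
    if (lo < 0) lo = 0;
    if (lo > n - width) lo = n - width;
    if (cur_lo < 0) {
      buf.assign(x.begin() + lo, x.begin() + lo + width);
      std::sort(buf.begin(), buf.end());
      cur_lo = lo;
    } else {
      while (cur_lo < lo) {
        // slide window right: drop x[cur_lo], add x[cur_lo + width]
        std::vector<double>::iterator it =
          std::lower_bound(buf.begin(), buf.end(), x[cur_lo]);
        buf.erase(it);
        double add = x[cur_lo + width];
        buf.insert(std::upper_bound(buf.begin(), buf.end(), add), add);
        ++cur_lo;
      }
    }
    // remove self, compute stats on the remaining width-1 values
    std::vector<double> nb(buf);
    std::vector<double>::iterator self =
      std::lower_bound(nb.begin(), nb.end(), x[i]);
    nb.erase(self);
    out(i, 0) = quantile7(nb, 0.5);
    out(i, 1) = (quantile7(nb, 0.75) - quantile7(nb, 0.25)) / 2.0;
  }
  return out;
}
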