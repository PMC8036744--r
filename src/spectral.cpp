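#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Centered rolling minimum with truncated windows at the edges.
static void rolling_min(const double* x, double* out, int n, int width) {
  int half = width / 2;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    double m = x[lo];
    for (int j = lo + 1; j <= hi; ++j)
      if (x[j] < m) m = x[j];
    out[i] = m;
  }
}

static void rolling_mean(const double* x, double* out, int n, int width) {
  int half = width / 2;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    double s = 0.0;
    for (int j = lo; j <= hi; ++j) s += x[j];
    out[i] = s / (hi - lo + 1);
  }
}

// Convolution baseline removal: the baseline is the moving-average-smoothed
// lower envelope (rolling minimum) of each spectrum; it is subtracted and the
// result clamped at zero.  Rows are spectra.
// [[Rcpp::export]]
NumericMatrix cpp_remove_baseline(NumericMatrix X, int width) {
  int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), env(nc), base(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = X(i, j);
    rolling_min(row.data(), env.data(), nc, width);
    rolling_mean(env.data(), base.data(), nc, width);
    for (int j = 0; j < nc; ++j) {
      double v = row[j] - base[j];
      out(i, j) = v > 0.0 ? v : 0.0;
    }
  }
  return out;
}

static double mad_scaled(std::vector<double> v) {
  int n = (int) v.size();
  if (n == 0) return 0.0;
  std::vector<double> w(v);
  std::nth_element(w.begin(), w.begin() + n / 2, w.end());
  double med = w[n / 2];
  if (n % 2 == 0) {
    std::nth_element(w.begin(), w.begin() + n / 2 - 1, w.end());
    med = (med + w[n / 2 - 1]) / 2.0;
  }
  for (int i = 0; i < n; ++i) w[i] = std::fabs(v[i] - med);
  std::nth_element(w.begin(), w.begin() + n / 2, w.end());
  double mad = w[n / 2];
  if (n % 2 == 0) {
    std::nth_element(w.begin(), w.begin() + n / 2 - 1, w.end());
    mad = (mad + w[n / 2 - 1]) / 2.0;
  }
  return 1.4826 * mad;
}

// Per-spectrum local-maxima peak detection with a MAD-based noise estimate.
// A point is a peak when it exceeds its left neighbour, is >= its right
// neighbour, and its intensity exceeds snr * MAD(spectrum).  Returns the
// pooled peak positions, intensities and 1-based spectrum indices.
// [[Rcpp::export]]
List cpp_detect_peaks(NumericMatrix X, NumericVector mz, double snr) {
  int nr = X.nrow(), nc = X.ncol();
  std::vector<double> pk_mz, pk_int;
  std::vector<int> pk_spec;
  std::vector<double> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = X(i, j);
    double noise = mad_scaled(row);
    double thr = snr * noise;
    for (int j = 1; j < nc - 1; ++j) {
      double v = row[j];
      if (v > row[j - 1] && v >= row[j + 1] && v > thr) {
        pk_mz.push_back(mz[j]);
        pk_int.push_back(v);
        pk_spec.push_back(i + 1);
      }
    }
  }
  return List::create(_["mz"] = wrap(pk_mz), _["intensity"] = wrap(pk_int),
                      _["spectrum"] = wrap(pk_spec));
}

// Maximum intensity within a column range per spectrum; ranges are 1-based
// inclusive, a range with start > end yields 0 (no signal near that center).
// [[Rcpp::export]]
NumericMatrix cpp_extract_features(NumericMatrix X, IntegerVector start,
                                   IntegerVector end) {
  int nr = X.nrow(), p = start.size();
  NumericMatrix out(nr, p);
  for (int k = 0; k < p; ++k) {
    int lo = start[k] - 1, hi = end[k] - 1;
    if (lo > hi) continue;
    for (int i = 0; i < nr; ++i) {
      double m = 0.0;
      for (int j = lo; j <= hi; ++j)
        if (X(i, j) > m) m = X(i, j);
      out(i, k) = m;
    }
  }
  return out;
}
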