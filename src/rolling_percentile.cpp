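#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Type-7 quantile (R default) of a sorted window.
static inline double quantile7(const std::vector<double>& w, double p) {
    const int n = (int)w.size();
    if (n == 1) return w[0];
    double h = (n - 1) * p;
    int lo = (int)std::floor(h);
    double frac = h - lo;
    if (lo >= n - 1) return w[n - 1];
    return w[lo] + frac * (w[lo + 1] - w[lo]);
}

static inline void sorted_insert(std::vector<double>& w, double x) {
    w.insert(std::upper_bound(w.begin(), w.end(), x), x);
}

static inline void sorted_erase(std::vector<double>& w, double x) {
    auto it = std::lower_bound(w.begin(), w.end(), x);
    w.erase(it);
}

//' Rolling percentile with truncated (shrinking) windows at the edges.
//'
//' @param x numeric vector
//' @param halfwin half window width in samples
//' @param p percentile in [0, 1]
//' @return numeric vector of windowed percentiles, same length as x
//' @keywords internal
// [[Rcpp::export(name = ".rollingPercentile")]]
NumericVector rollingPercentile(NumericVector x, int halfwin, double p) {
    const int n = x.size();
    NumericVector out(n);
    if (n == 0) return out;
    std::vector<double> w;
    w.reserve(2 * halfwin + 2);
    // initial window for i = 0: [0, min(halfwin, n-1)]
    int right = std::min(halfwin, n - 1);
    for (int j = 0; j <= right; ++j) sorted_insert(w, x[j]);
    int left = 0;
    for (int i = 0; i < n; ++i) {
        int new_left = std::max(0, i - halfwin);
        int new_right = std::min(n - 1, i + halfwin);
        while (left < new_left) { sorted_erase(w, x[left]); ++left; }
        while (right < new_right) { ++right; sorted_insert(w, x[right]); }
        out[i] = quantile7(w, p);
    }
    return out;
}
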