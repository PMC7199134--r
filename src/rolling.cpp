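#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rolling mean/median with the package's missingness rule: windows with
// more than 50% missing yield NA, otherwise the statistic over the
// non-missing entries. Only full windows are evaluated; the rest is NA.
// align: 0 = right (trailing), 1 = center (window i - floor(w/2) ..
// i + w - 1 - floor(w/2)).
// [[Rcpp::export(name = ".roll_stat_c")]]
NumericVector roll_stat_c(NumericVector x, int w, bool use_median, int align) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  if (w < 1 || w > n) return out;
  int lead = (align == 1) ? w / 2 : (w - 1);
  std::vector<double> buf;
  buf.reserve(w);
  for (int i = 0; i + w <= n; ++i) {  // window covers [i, i + w - 1]
    buf.clear();
    for (int j = i; j < i + w; ++j) {
      if (!NumericVector::is_na(x[j])) buf.push_back(x[j]);
    }
    int pos = i + lead;
    if (pos < 0 || pos >= n) continue;
    int miss = w - (int)buf.size();
    if (2 * miss > w || buf.empty()) continue;  // > 50% missing -> NA
    if (!use_median) {
      double s = 0.0;
      for (double v : buf) s += v;
      out[pos] = s / buf.size();
    } else {
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double hi = buf[m];
      if (buf.size() % 2 == 1) {
        out[pos] = hi;
      } else {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        out[pos] = (lo + hi) / 2.0;
      }
    }
  }
  return out;
}

// Per-minute (block) range of a channel: max - min over consecutive
// blocks of spm samples. Used by the non-wear stillness rule.
// [[Rcpp::export(name = ".block_range_c")]]
NumericVector block_range_c(NumericVector x, int spm, int n_blocks) {
  NumericVector out(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    double lo = x[b * spm], hi = lo;
    for (int j = 1; j < spm; ++j) {
      double v = x[b * spm + j];
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    out[b] = hi - lo;
  }
  return out;
}

// Per-minute movement: sqrt of the within-block sum of squared successive
// differences across the three axes (block = spm samples; differences
// across block edges are excluded).
// [[Rcpp::export(name = ".block_movement_c")]]
NumericVector block_movement_c(NumericVector x, NumericVector y,
                               NumericVector z, int spm, int n_blocks) {
  NumericVector out(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    double s = 0.0;
    int i0 = b * spm;
    for (int j = 1; j < spm; ++j) {
      double dx = x[i0 + j] - x[i0 + j - 1];
      double dy = y[i0 + j] - y[i0 + j - 1];
      double dz = z[i0 + j] - z[i0 + j - 1];
      s += dx * dx + dy * dy + dz * dz;
    }
    out[b] = std::sqrt(s);
  }
  return out;
}
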