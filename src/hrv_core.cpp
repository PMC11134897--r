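#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Beat emission from a modulated point process: the instantaneous interval
// m(t) is evaluated at the current beat time and the next beat is placed
// one interval later. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector cpp_generate_beats(double duration_s, double rr0_ms,
                                 double a_lf, double a_hf,
                                 double f_lf, double f_resp,
                                 double phi, double psi,
                                 double noise_sd_ms) {
  if (duration_s <= 0 || rr0_ms <= 0)
    stop("duration and base RR must be positive");
  if (a_lf + a_hf >= 1)
    stop("modulation amplitudes must sum to less than 1");
  std::vector<double> out;
  out.reserve((size_t)(duration_s * 1000.0 / rr0_ms) + 16);
  double t = 0.0;
  const double two_pi = 2.0 * M_PI;
  while (t < duration_s) {
    double m = rr0_ms * (1.0 + a_lf * std::sin(two_pi * f_lf * t + phi) +
                               a_hf * std::sin(two_pi * f_resp * t + psi));
    if (noise_sd_ms > 0) m += R::rnorm(0.0, noise_sd_ms);
    if (m < 1.0) m = 1.0;  // jitter guard; unreachable with sane settings
    out.push_back(m);
    t += m / 1000.0;
  }
  return wrap(out);
}

// Sequential NN filter. Label codes: 0 normal, 1 ectopic, 2 artifact,
// 3 unknown. An interval keeps a non-normal input label (rule a); a
// normal-labelled interval is flagged as artifact when outside the
// physiological window (rule c) or when it deviates from the median of
// the previous w intervals that have survived as normal by more than
// `threshold` fractionally (rule b; applied with the available history
// when fewer than w normals precede it, skipped when none do).
// [[Rcpp::export]]
IntegerVector cpp_clean_labels(NumericVector intervals, IntegerVector labels,
                               int w, double threshold,
                               double lo_ms, double hi_ms) {
  int n = intervals.size();
  if (n == 0) stop("empty series");
  if (w < 1 || w > n) stop("median window must be in [1, length(series)]");
  IntegerVector out(n);
  std::vector<double> hist;  // surviving normal intervals, in order
  hist.reserve(n);
  std::vector<double> buf(w);
  for (int i = 0; i < n; ++i) {
    int lab = labels[i];
    double x = intervals[i];
    if (lab != 0) {
      out[i] = lab;
      continue;
    }
    if (x < lo_ms || x > hi_ms) {
      out[i] = 2;
      continue;
    }
    int h = (int)hist.size();
    int m = h < w ? h : w;
    if (m > 0) {
      for (int j = 0; j < m; ++j) buf[j] = hist[h - m + j];
      std::sort(buf.begin(), buf.begin() + m);
      double med = (m % 2 == 1) ? buf[m / 2]
                                : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
      if (std::abs(x - med) > threshold * med) {
        out[i] = 2;
        continue;
      }
    }
    out[i] = 0;
    hist.push_back(x);
  }
  return out;
}
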