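#' Spectral analysis settings
#'
#' @param resample_hz uniform resampling rate for the tachogram (Hz).
#' @param window_len Welch window length in samples (~85 s at 3 Hz with the
#'   default 256).
#' @param overlap fractional overlap between successive windows.
#' @param window_kind taper; only `"hann"` is implemented.
#' @param detrend per-window detrending; only `"constant"` (mean removal)
#'   is implemented.
#' @param nu_denominator denominator for normalized units: `"lf_hf"`
#'   (LF + HF) or `"total"` (all power above 0 Hz).
#' @return list of class `hrv_settings`.
#' @export
hrv_settings <- function(resample_hz = 3, window_len = 256, overlap = 0.5,
                         window_kind = "hann", detrend = "constant",
                         nu_denominator = c("lf_hf", "total")) {
  stopifnot(resample_hz > 0, window_len >= 8, overlap >= 0, overlap < 1)
  window_kind <- match.arg(window_kind, "hann")
  detrend <- match.arg(detrend, "constant")
  structure(list(resample_hz = resample_hz, window_len = as.integer(window_len),
                 overlap = overlap, window_kind = window_kind,
                 detrend = detrend,
                 nu_denominator = match.arg(nu_denominator)),
            class = "hrv_settings")
}

#' Time-domain HRV indexes
#'
#' Mean NN, mean heart rate (60000 / mean NN), SDNN as the sample standard
#' deviation (denominator N - 1), and pNN50 as the percentage of successive
#' NN differences strictly greater than 50 ms.
#'
#' @param segment an [nn_segment()] (or bare numeric vector of NN ms).
#' @return Named list: `mean_nn_ms`, `mean_hr_bpm`, `sdnn_ms`, `pnn50_pct`.
#' @export
time_domain <- function(segment) {
  nn <- if (inherits(segment, "nn_segment")) segment$nn_ms else as.numeric(segment)
  if (length(nn) < 2) stop("insufficient data: need at least 2 NN intervals")
  mean_nn <- mean(nn)
  d <- diff(nn)
  list(mean_nn_ms = mean_nn,
       mean_hr_bpm = 60000 / mean_nn,
       sdnn_ms = sd(nn),
       pnn50_pct = 100 * sum(abs(d) > 50) / length(d))
}

#' Resample an NN tachogram onto a uniform grid
#'
#' The tachogram is the set of points (end time of each NN interval, NN
#' value); values between points are linearly interpolated and sampled at
#' `rate_hz` from the first point to the last (grid `t0, t0 + 1/rate, ...`).
#'
#' @param segment an [nn_segment()].
#' @param rate_hz sampling rate, Hz.
#' @return list with `t_s` (grid times) and `x_ms` (interpolated NN values).
#' @export
resample_tachogram <- function(segment, rate_hz = 3) {
  stopifnot(inherits(segment, "nn_segment"), rate_hz > 0)
  if (length(segment$nn_ms) < 2) stop("need at least 2 tachogram points")
  t0 <- segment$end_times_s[1]
  tn <- segment$end_times_s[length(segment$end_times_s)]
  grid <- seq(t0, tn, by = 1 / rate_hz)
  x <- approx(segment$end_times_s, segment$nn_ms, xout = grid,
              method = "linear")$y
  list(t_s = grid, x_ms = x, rate_hz = rate_hz)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch periodogram PSD estimate
#'
#' Averaged modified periodograms: the series is split into
#' `window_len`-sample windows with the configured overlap, each window is
#' mean-detrended, Hann-tapered and Fourier transformed, and the one-sided
#' PSD is normalized so its integral over frequency matches the variance of
#' the detrended samples (up to taper-induced leakage).
#'
#' @param samples numeric vector (uniformly sampled tachogram, ms) or the
#'   list returned by [resample_tachogram()].
#' @param settings an [hrv_settings()].
#' @param rate_hz sampling rate; ignored when `samples` carries one.
#' @return list of class `spectrum_estimate` with `frequencies_hz`,
#'   `psd_ms2_per_hz`, `settings`, and `n_windows`.
#' @export
welch_psd <- function(samples, settings = hrv_settings(), rate_hz = NULL) {
  if (is.list(samples)) {
    rate_hz <- samples$rate_hz
    samples <- samples$x_ms
  }
  rate_hz <- rate_hz %||% settings$resample_hz
  n <- length(samples)
  nw <- settings$window_len
  if (n < 2) stop("too few samples for spectral estimation")
  if (n < nw) {
    warning("series shorter than the Welch window; using a single window")
    nw <- n
  }
  step <- max(1L, as.integer(floor(nw * (1 - settings$overlap))))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- hann_window(nw)
  scale <- rate_hz * sum(w^2)
  nfreq <- nw %/% 2 + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- samples[s0:(s0 + nw - 1L)]
    seg <- seg - mean(seg)
    y <- fft(seg * w)[1:nfreq]
    p <- (Mod(y)^2) / scale
    # one-sided: double interior bins (not DC; not Nyquist when nw is even)
    dbl <- 2:(nfreq - if (nw %% 2 == 0) 1 else 0)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  structure(list(frequencies_hz = (0:(nfreq - 1)) * rate_hz / nw,
                 psd_ms2_per_hz = acc / length(starts),
                 settings = settings, n_windows = length(starts)),
            class = "spectrum_estimate")
}

# Trapezoidal integral of the PSD between two frequencies, with the PSD
# linearly interpolated at the exact band edges.
band_integral <- function(freq, psd, lo, hi) {
  if (hi <= freq[1] || lo >= freq[length(freq)]) return(0)
  lo <- max(lo, freq[1]); hi <- min(hi, freq[length(freq)])
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  p <- c(approx(freq, psd, lo)$y, psd[inside], approx(freq, psd, hi)$y)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' LF/HF band powers and normalized units
#'
#' Band power is the trapezoidal integral of the PSD over 0.04-0.15 Hz
#' (LF) and 0.15-0.4 Hz (HF); the 0.15 Hz boundary belongs to HF.
#' Normalized units divide by LF + HF by default. An undefined ratio (zero
#' denominator) is returned as `NA`, never as an infinity.
#'
#' @param spectrum a [welch_psd()] result.
#' @param nu_denominator see [hrv_settings()]; defaults to the setting
#'   recorded in `spectrum`.
#' @return Named list: `lf_power_ms2`, `hf_power_ms2`, `lf_nu`, `hf_nu`,
#'   `log10_lf_hf`.
#' @export
band_powers <- function(spectrum, nu_denominator = NULL) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  f <- spectrum$frequencies_hz
  p <- spectrum$psd_ms2_per_hz
  if (f[length(f)] < 0.4)
    stop("spectrum must cover frequencies up to 0.4 Hz")
  nu_den <- nu_denominator %||% spectrum$settings$nu_denominator
  lf <- band_integral(f, p, 0.04, 0.15)
  hf <- band_integral(f, p, 0.15, 0.4)
  den <- if (identical(nu_den, "total"))
    band_integral(f, p, f[2], f[length(f)]) else lf + hf
  list(lf_power_ms2 = lf, hf_power_ms2 = hf,
       lf_nu = if (den > 0) 100 * lf / den else NA_real_,
       hf_nu = if (den > 0) 100 * hf / den else NA_real_,
       log10_lf_hf = if (lf > 0 && hf > 0) log10(lf / hf) else NA_real_)
}

#' Poincare plot descriptors
#'
#' Plots each NN interval against the next and measures the dispersion of
#' the cloud along the axes of the fitted ellipse, which lie on and
#' perpendicular to the identity line. Rotating the pairs by 45 degrees,
#' `u = (NN[i+1] - NN[i]) / sqrt(2)` and `v = (NN[i+1] + NN[i]) / sqrt(2)`,
#' gives SD1 = sd(u) (short-term, beat-to-beat variability) and
#' SD2 = sd(v) (long-term variability) directly.
#'
#' @param segment an [nn_segment()] or numeric NN vector (>= 3 intervals).
#' @return Named list: `sd1_ms`, `sd2_ms`, `sd2_sd1_ratio`, `sd1_sd2_ratio`
#'   (ratios `NA` when a denominator vanishes).
#' @export
poincare <- function(segment) {
  nn <- if (inherits(segment, "nn_segment")) segment$nn_ms else as.numeric(segment)
  if (length(nn) < 3) stop("insufficient data: need at least 3 NN intervals")
  x <- nn[-length(nn)]
  y <- nn[-1]
  sd1 <- sd((y - x) / sqrt(2))
  sd2 <- sd((y + x) / sqrt(2))
  list(sd1_ms = sd1, sd2_ms = sd2,
       sd2_sd1_ratio = if (sd1 > 0) sd2 / sd1 else NA_real_,
       sd1_sd2_ratio = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' All HRV indexes for one segment
#'
#' Aggregates the time-domain, spectral and Poincare computations into the
#' full index set reported per subject and condition.
#'
#' @param segment an [nn_segment()].
#' @param settings an [hrv_settings()].
#' @return list of class `hrv_indexes` with fields `mean_nn_ms`,
#'   `mean_hr_bpm`, `sdnn_ms`, `pnn50_pct`, `lf_power_ms2`, `hf_power_ms2`,
#'   `lf_nu`, `hf_nu`, `log10_lf_hf`, `sd1_ms`, `sd2_ms`, `sd2_sd1_ratio`,
#'   `sd1_sd2_ratio`, plus a `settings` attribute recording provenance.
#' @export
compute_hrv <- function(segment, settings = hrv_settings()) {
  stopifnot(inherits(segment, "nn_segment"))
  td <- time_domain(segment)
  sp <- band_powers(welch_psd(resample_tachogram(segment,
                                                 settings$resample_hz),
                              settings))
  pc <- poincare(segment)
  structure(c(td, sp, pc), class = "hrv_indexes",
            settings = settings,
            identity = segment[c("subject_id", "timepoint", "condition")])
}

#' Names of the HRV index fields
#' @return character vector in reporting order.
#' @export
hrv_index_names <- function() {
  c("mean_nn_ms", "mean_hr_bpm", "sdnn_ms", "pnn50_pct",
    "lf_power_ms2", "hf_power_ms2", "lf_nu", "hf_nu", "log10_lf_hf",
    "sd1_ms", "sd2_ms", "sd2_sd1_ratio", "sd1_sd2_ratio")
}
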