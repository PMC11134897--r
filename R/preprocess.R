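#' NN filter configuration
#'
#' @param median_window number of preceding accepted-normal intervals whose
#'   running median anchors the deviation rule.
#' @param threshold maximal fractional deviation from that median before an
#'   interval is flagged.
#' @param window_ms two-element physiological window (ms); intervals
#'   outside it are flagged regardless of context.
#' @return A list of class `nn_filter_config`.
#' @export
nn_filter_config <- function(median_window = 11, threshold = 0.20,
                             window_ms = c(300, 2000)) {
  stopifnot(median_window >= 1, threshold > 0, length(window_ms) == 2,
            window_ms[1] > 0, window_ms[2] > window_ms[1])
  structure(list(median_window = as.integer(median_window),
                 threshold = threshold, window_ms = window_ms),
            class = "nn_filter_config")
}

#' Flag non-sinus intervals in an RR series
#'
#' Relabels intervals so that downstream analysis uses sinus (NN) beats
#' only. An interval is flagged non-normal when (a) it already carries an
#' ectopic/artifact annotation, (b) it deviates from the running median of
#' the previous `median_window` accepted-normal intervals by more than the
#' fractional `threshold`, or (c) it falls outside the absolute
#' physiological window. Flagged intervals are excluded, never corrected or
#' interpolated; the filter is a single forward pass and is idempotent.
#'
#' @param series an [rr_series()].
#' @param filter_config an [nn_filter_config()].
#' @return The input series with updated `labels` and attributes
#'   `n_excluded` (newly plus previously flagged count) and `n_flagged_new`
#'   (flagged by this pass).
#' @export
clean_to_nn <- function(series, filter_config = nn_filter_config()) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$intervals_ms)
  if (n == 0) stop("empty series")
  if (filter_config$median_window > n)
    stop("median window (", filter_config$median_window,
         ") exceeds series length (", n, ")")
  code_in <- match(series$labels, .beat_labels) - 1L
  code_out <- cpp_clean_labels(series$intervals_ms, code_in,
                               filter_config$median_window,
                               filter_config$threshold,
                               filter_config$window_ms[1],
                               filter_config$window_ms[2])
  out <- series
  out$labels <- .beat_labels[code_out + 1L]
  attr(out, "n_excluded") <- sum(out$labels != "normal")
  attr(out, "n_flagged_new") <- sum(out$labels != "normal" &
                                      series$labels == "normal")
  out
}

#' Select the stable standardized NN segment
#'
#' From a cleaned series, takes the normal-labelled intervals whose beat
#' time is at or after `skip_s` (discarding the initial adaptation period)
#' and scans every contiguous window of `L` NN intervals, choosing the one
#' with minimal SDNN -- the operational definition of a "stable" segment.
#' Ties go to the earliest window. With the default L = 300 a segment
#' covers roughly five minutes.
#'
#' @param series an [rr_series()], normally after [clean_to_nn()].
#' @param L segment length in NN intervals.
#' @param skip_s seconds discarded from the start of the recording.
#' @return An [nn_segment()] of exactly `L` intervals.
#' @export
select_segment <- function(series, L = 300, skip_s = 180) {
  stopifnot(inherits(series, "rr_series"), L >= 2, skip_s >= 0)
  ok <- series$labels == "normal" & series$beat_times_s >= skip_s
  nn <- series$intervals_ms[ok]
  tt <- series$beat_times_s[ok]
  if (length(nn) < L)
    stop(sprintf(
      "insufficient data: %d normal intervals after %g s (need %d) [%s/%s/%s]",
      length(nn), skip_s, L, series$subject_id, series$timepoint,
      series$condition))
  # rolling sample SD over all candidate starts via cumulative sums
  m <- length(nn) - L + 1
  cs <- cumsum(c(0, nn))
  cs2 <- cumsum(c(0, nn^2))
  s <- cs[(L + 1):(L + m)] - cs[1:m]
  s2 <- cs2[(L + 1):(L + m)] - cs2[1:m]
  v <- (s2 - s^2 / L) / (L - 1)
  start <- which.min(pmax(v, 0))  # which.min takes the earliest tie
  idx <- start:(start + L - 1)
  nn_segment(nn[idx], tt[idx], condition = series$condition,
             timepoint = series$timepoint, subject_id = series$subject_id)
}
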