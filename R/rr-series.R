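#' @useDynLib hrvreact, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft sd median var aov chisq.test fisher.test
#'   cor.test ks.test t.test pchisq pnorm pt qnorm rnorm runif rbinom
#'   setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

.conditions <- c("supine", "standing", "breathing")
.timepoints <- c("baseline", "followup")
.beat_labels <- c("normal", "ectopic", "artifact", "unknown")

#' Annotated RR-interval series
#'
#' Container for one beat-to-beat recording of a single subject in a single
#' physiological condition at one timepoint. Beat times are the cumulative
#' sums of the intervals, i.e. each interval is stamped with the time of the
#' beat that ends it.
#'
#' @param intervals_ms numeric vector of positive RR intervals in
#'   milliseconds, in temporal order.
#' @param labels per-interval beat annotation, one of `"normal"`,
#'   `"ectopic"`, `"artifact"`, `"unknown"`. Recycled if length 1.
#' @param condition recording condition: `"supine"`, `"standing"` or
#'   `"breathing"`.
#' @param timepoint `"baseline"` or `"followup"`.
#' @param subject_id subject identifier string.
#' @return An object of class `rr_series`: a list with elements
#'   `intervals_ms`, `beat_times_s` (cumulative, seconds), `labels`,
#'   `condition`, `timepoint`, `subject_id`.
#' @export
rr_series <- function(intervals_ms, labels = "normal",
                      condition = "supine", timepoint = "baseline",
                      subject_id = "S001") {
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) == 0) stop("empty RR series")
  if (any(!is.finite(intervals_ms)) || any(intervals_ms <= 0))
    stop("all RR intervals must be finite and positive")
  labels <- rep_len(as.character(labels), length(intervals_ms))
  if (!all(labels %in% .beat_labels))
    stop("labels must be one of: ", paste(.beat_labels, collapse = ", "))
  condition <- match.arg(condition, .conditions)
  timepoint <- match.arg(timepoint, .timepoints)
  structure(
    list(intervals_ms = intervals_ms,
         beat_times_s = cumsum(intervals_ms) / 1000,
         labels = labels,
         condition = condition, timepoint = timepoint,
         subject_id = subject_id),
    class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s / %s / %s: %d beats over %.1f s (%d non-normal)\n",
              x$subject_id, x$timepoint, x$condition,
              length(x$intervals_ms), x$beat_times_s[length(x$beat_times_s)],
              sum(x$labels != "normal")))
  invisible(x)
}

#' Standardized NN segment
#'
#' A fixed-count window of consecutive normal-to-normal (sinus) intervals,
#' the unit on which all HRV indexes are computed. Keeping the interval
#' count fixed across subjects and conditions avoids estimator differences
#' driven purely by series length.
#'
#' @param nn_ms normal-to-normal intervals in milliseconds.
#' @param end_times_s beat time (seconds, recording clock) at which each NN
#'   interval ends; strictly increasing. Gaps larger than the interval occur
#'   where excluded beats were dropped.
#' @param condition,timepoint,subject_id recording identity, as in
#'   [rr_series()].
#' @return Object of class `nn_segment`.
#' @export
nn_segment <- function(nn_ms, end_times_s,
                       condition = "supine", timepoint = "baseline",
                       subject_id = "S001") {
  nn_ms <- as.numeric(nn_ms)
  end_times_s <- as.numeric(end_times_s)
  if (length(nn_ms) != length(end_times_s))
    stop("nn_ms and end_times_s must have equal length")
  if (any(diff(end_times_s) <= 0)) stop("end times must be strictly increasing")
  if (any(nn_ms <= 0)) stop("NN intervals must be positive")
  structure(
    list(nn_ms = nn_ms, end_times_s = end_times_s,
         start_time_s = end_times_s[1] - nn_ms[1] / 1000,
         condition = condition, timepoint = timepoint,
         subject_id = subject_id),
    class = "nn_segment")
}

#' @export
print.nn_segment <- function(x, ...) {
  cat(sprintf("<nn_segment> %s / %s / %s: %d NN intervals from t = %.1f s\n",
              x$subject_id, x$timepoint, x$condition,
              length(x$nn_ms), x$start_time_s))
  invisible(x)
}

#' Read a plain-text tachogram file
#'
#' The tachogram dialect is one interval per line in milliseconds, an
#' optional second whitespace-separated column with the beat label, and
#' `#`-prefixed comment lines (ignored, except that `key=value` comments
#' for subject/condition/timepoint are honoured when present).
#'
#' @param path file path.
#' @param condition,timepoint,subject_id identity used when the file
#'   carries no metadata comments.
#' @return An [rr_series()].
#' @export
read_tachogram <- function(path, condition = "supine",
                           timepoint = "baseline", subject_id = NULL) {
  lines <- readLines(path)
  meta <- list(condition = condition, timepoint = timepoint,
               subject_id = subject_id %||% sub("\\..*$", "", basename(path)))
  com <- grep("^\\s*#", lines, value = TRUE)
  for (key in c("subject_id", "condition", "timepoint")) {
    hit <- grep(paste0(key, "\\s*="), com, value = TRUE)
    if (length(hit))
      meta[[key]] <- trimws(sub(paste0(".*", key, "\\s*=\\s*"), "", hit[1]))
  }
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(dat)) stop("no interval lines in ", path)
  parts <- strsplit(trimws(dat), "\\s+")
  iv <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), 0)
  if (any(is.na(iv))) stop("non-numeric interval in ", path)
  lab <- vapply(parts, function(p) if (length(p) > 1) p[2] else "normal", "")
  rr_series(iv, labels = lab, condition = meta$condition,
            timepoint = meta$timepoint, subject_id = meta$subject_id)
}

#' Write a tachogram file
#'
#' Emits the same dialect [read_tachogram()] parses; labels other than
#' `"normal"` are written as a second column.
#'
#' @param series an [rr_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tachogram <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  hdr <- c(sprintf("# subject_id=%s", series$subject_id),
           sprintf("# timepoint=%s", series$timepoint),
           sprintf("# condition=%s", series$condition),
           "# columns: interval_ms [label]")
  body <- ifelse(series$labels == "normal",
                 sprintf("%.6f", series$intervals_ms),
                 sprintf("%.6f %s", series$intervals_ms, series$labels))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
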