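# Brute-force reference implementations used to validate the package's
# estimators. These are deliberately written as plain loops, independent of
# the code paths they check.

oracle_time_domain <- function(nn) {
  n <- length(nn)
  s <- 0
  for (x in nn) s <- s + x
  m <- s / n
  ss <- 0
  for (x in nn) ss <- ss + (x - m)^2
  cnt <- 0
  for (i in 1:(n - 1)) if (abs(nn[i + 1] - nn[i]) > 50) cnt <- cnt + 1
  list(mean_nn_ms = m, mean_hr_bpm = 60000 / m,
       sdnn_ms = sqrt(ss / (n - 1)), pnn50_pct = 100 * cnt / (n - 1))
}

oracle_poincare <- function(nn) {
  n <- length(nn)
  u <- v <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    u[i] <- (nn[i + 1] - nn[i]) / sqrt(2)
    v[i] <- (nn[i + 1] + nn[i]) / sqrt(2)
  }
  lsd <- function(z) {
    m <- sum(z) / length(z)
    sqrt(sum((z - m)^2) / (length(z) - 1))
  }
  list(sd1_ms = lsd(u), sd2_ms = lsd(v))
}

# Sequential re-evaluation of the NN filter rules on every interval.
oracle_clean_labels <- function(intervals, labels, w = 11, threshold = 0.20,
                                lo = 300, hi = 2000) {
  out <- character(length(intervals))
  hist <- numeric(0)
  for (i in seq_along(intervals)) {
    if (labels[i] != "normal") { out[i] <- labels[i]; next }
    x <- intervals[i]
    if (x < lo || x > hi) { out[i] <- "artifact"; next }
    m <- min(w, length(hist))
    if (m > 0) {
      med <- median(hist[(length(hist) - m + 1):length(hist)])
      if (abs(x - med) > threshold * med) { out[i] <- "artifact"; next }
    }
    out[i] <- "normal"
    hist <- c(hist, x)
  }
  out
}

# Exhaustive minimum-SDNN window scan.
oracle_select_start <- function(nn, L) {
  best <- Inf; best_i <- NA
  for (i in 1:(length(nn) - L + 1)) {
    s <- sd(nn[i:(i + L - 1)])
    if (s < best - 1e-12) { best <- s; best_i <- i }
  }
  best_i
}

# Tie-corrected Mann-Whitney pair counting.
oracle_auc <- function(scores, labels, direction = "positive_if_le") {
  cases <- scores[labels]; ctrl <- scores[!labels]
  conc <- 0; ties <- 0
  for (a in cases) for (b in ctrl) {
    better <- if (direction == "positive_if_le") a < b else a > b
    if (better) conc <- conc + 1 else if (a == b) ties <- ties + 1
  }
  (conc + 0.5 * ties) / (length(cases) * length(ctrl))
}

# Sum-of-squares decomposition for the subject-blocked one-way ANOVA.
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_subj <- k * sum((rowMeans(mat) - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_res / ((k - 1) * (n - 1)))
  list(F = f, p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# Random plausible NN segment for oracle equivalence checks.
random_segment <- function(n = 300, base = NULL) {
  base <- base %||% runif(1, 700, 1100)
  nn <- base + cumsum(rnorm(n, 0, 8))
  nn <- pmax(nn, 350)
  nn_segment(nn, cumsum(nn) / 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
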