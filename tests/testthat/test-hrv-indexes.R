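test_that("time-domain indexes on hand-computable segments", {
  const <- time_domain(rep(1000, 300))
  expect_equal(const$mean_nn_ms, 1000)
  expect_equal(const$mean_hr_bpm, 60)
  expect_equal(const$sdnn_ms, 0)
  expect_equal(const$pnn50_pct, 0)

  td <- time_domain(c(1000, 1060, 1010))
  expect_equal(td$pnn50_pct, 50)  # -50 does not exceed 50 strictly
  expect_equal(td$mean_nn_ms, 3070 / 3)
  expect_equal(td$sdnn_ms, sqrt(2066.666666666667 / 2), tolerance = 1e-12)
  expect_error(time_domain(1000), "insufficient")
})

test_that("time-domain and Poincare estimators match loop oracles", {
  set.seed(1001)
  for (rep in 1:200) {
    seg <- random_segment(sample(50:400, 1))
    td <- time_domain(seg)
    o <- oracle_time_domain(seg$nn_ms)
    for (f in names(o)) expect_equal(td[[f]], o[[f]], tolerance = 1e-12)
    pc <- poincare(seg)
    op <- oracle_poincare(seg$nn_ms)
    expect_equal(pc$sd1_ms, op$sd1_ms, tolerance = 1e-12)
    expect_equal(pc$sd2_ms, op$sd2_ms, tolerance = 1e-12)
  }
})

test_that("resampling is exact on constants and linear tachograms", {
  seg <- nn_segment(rep(1000, 50), cumsum(rep(1000, 50)) / 1000)
  rs <- resample_tachogram(seg, 3)
  expect_true(all(rs$x_ms == 1000))

  two <- nn_segment(c(800, 1000), c(0.0001, 1.0001))
  # shift times so the points sit at t = 0 and t = 1 exactly
  two$end_times_s <- c(0, 1)
  rs2 <- resample_tachogram(two, 3)
  expect_equal(rs2$x_ms, c(800, 800 + 200 / 3, 800 + 400 / 3, 1000),
               tolerance = 1e-12)

  lin <- nn_segment(seq(800, 1100, length.out = 100),
                    seq(0, 99, length.out = 100) + 5)
  rs3 <- resample_tachogram(lin, 3)
  slope <- (1100 - 800) / 99
  expect_equal(rs3$x_ms, 800 + slope * (rs3$t_s - 5), tolerance = 1e-12)
})

test_that("Welch PSD integrates to the sample variance for white noise", {
  set.seed(55)
  rel_err <- replicate(100, {
    x <- rnorm(900, 1000, 30)
    sp <- welch_psd(x, hrv_settings(), rate_hz = 3)
    f <- sp$frequencies_hz; p <- sp$psd_ms2_per_hz
    integral <- sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
    integral / var(x)
  })
  expect_lt(abs(mean(rel_err) - 1), 0.05)
})

test_that("Welch PSD recovers the analytic power of a pure sinusoid", {
  t <- seq(0, 300, by = 1 / 3)
  x <- 1000 + 50 * sin(2 * pi * 0.1 * t)
  sp <- welch_psd(x, hrv_settings(), rate_hz = 3)
  f <- sp$frequencies_hz; p <- sp$psd_ms2_per_hz
  total <- sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  expect_lt(abs(total - 1250) / 1250, 0.05)
  # power concentrated within one resolution bandwidth of 0.1 Hz
  rbw <- 3 / 256
  inband <- f >= 0.1 - 2 * rbw & f <= 0.1 + 2 * rbw
  conc <- sum(diff(f[inband]) * (p[inband][-1] + p[inband][-sum(inband)]) / 2)
  expect_gt(conc / total, 0.9)
})

test_that("null signal has an identically zero PSD", {
  sp <- welch_psd(rep(0, 600), hrv_settings(), rate_hz = 3)
  expect_true(all(sp$psd_ms2_per_hz == 0))
})

test_that("band powers: symmetric peaks, sinusoid oracle, out-of-band case", {
  f <- seq(0, 0.5, by = 0.01)
  p <- numeric(length(f))
  p[abs(f - 0.10) < 1e-9] <- 5
  p[abs(f - 0.25) < 1e-9] <- 5
  spec <- structure(list(frequencies_hz = f, psd_ms2_per_hz = p,
                         settings = hrv_settings()),
                    class = "spectrum_estimate")
  bp <- band_powers(spec)
  expect_equal(bp$lf_nu, 50)
  expect_equal(bp$hf_nu, 50)
  expect_equal(bp$log10_lf_hf, 0)

  t <- seq(0, 300, by = 1 / 3)
  x <- 1000 + 50 * sin(2 * pi * 0.1 * t)
  bs <- band_powers(welch_psd(x, hrv_settings(), rate_hz = 3))
  expect_lt(abs(bs$lf_power_ms2 - 1250) / 1250, 0.10)
  expect_gte(bs$lf_nu, 99)

  p2 <- numeric(length(f))
  p2[f > 0.4] <- 3
  spec2 <- structure(list(frequencies_hz = f, psd_ms2_per_hz = p2,
                          settings = hrv_settings()),
                     class = "spectrum_estimate")
  b2 <- band_powers(spec2)
  expect_equal(b2$lf_power_ms2, 0)
  expect_true(is.na(b2$lf_nu))
  expect_true(is.na(b2$log10_lf_hf))
})

test_that("Poincare descriptors: degenerate, alternating, and identity checks", {
  pc <- poincare(rep(1000, 300))
  expect_equal(pc$sd1_ms, 0)
  expect_equal(pc$sd2_ms, 0)
  expect_true(is.na(pc$sd2_sd1_ratio))

  alt <- poincare(rep(c(800, 1000), 150))
  expect_equal(alt$sd1_ms, 141.4, tolerance = 2 / 141.4)
  expect_lt(alt$sd2_ms, 2)

  set.seed(77)
  for (rep in 1:200) {
    seg <- random_segment(sample(200:400, 1))
    pc <- poincare(seg)
    nn <- seg$nn_ms
    pts <- c(nn[-length(nn)], nn[-1])  # all plotted coordinates
    lhs <- pc$sd1_ms^2 + pc$sd2_ms^2   # classical lag-1 descriptor identity
    expect_equal(lhs / (2 * var(pts)), 1, tolerance = 0.01)
  }
})

test_that("variability indexes are shift-invariant and reversal-invariant", {
  set.seed(31)
  seg <- random_segment(200)
  shifted <- seg; shifted$nn_ms <- seg$nn_ms + 250
  rev <- seg; rev$nn_ms <- base::rev(seg$nn_ms)
  a <- time_domain(seg); b <- time_domain(shifted); r <- time_domain(rev)
  expect_equal(a$sdnn_ms, b$sdnn_ms, tolerance = 1e-12)
  expect_equal(a$pnn50_pct, b$pnn50_pct)
  expect_equal(a$sdnn_ms, r$sdnn_ms, tolerance = 1e-12)
  expect_equal(a$pnn50_pct, r$pnn50_pct)
  pa <- poincare(seg); pb <- poincare(shifted); pr <- poincare(rev)
  expect_equal(pa$sd1_ms, pb$sd1_ms, tolerance = 1e-12)
  expect_equal(pa$sd2_ms, pb$sd2_ms, tolerance = 1e-12)
  expect_equal(pa$sd1_ms, pr$sd1_ms, tolerance = 1e-12)
  expect_equal(pa$sd2_ms, pr$sd2_ms, tolerance = 1e-12)
})

test_that("compute_hrv aggregates coherently and deterministically", {
  seg <- nn_segment(rep(900, 310), cumsum(rep(900, 310)) / 1000)
  hv <- compute_hrv(seg)
  expect_equal(hv$mean_hr_bpm, 60000 / 900)
  expect_equal(hv$sdnn_ms, 0)
  expect_true(is.na(hv$sd2_sd1_ratio))

  set.seed(8)
  seg2 <- random_segment(320)
  h1 <- compute_hrv(seg2)
  h2 <- compute_hrv(seg2)
  expect_identical(h1, h2)
  expect_equal(h1$mean_hr_bpm, 60000 / h1$mean_nn_ms, tolerance = 1e-9)
  expect_equal(h1$lf_nu + h1$hf_nu, 100, tolerance = 1e-9)
  expect_equal(h1$sd1_sd2_ratio, 1 / h1$sd2_sd1_ratio, tolerance = 1e-9)
})

test_that("standing-law parameters raise lf_nu relative to the supine law", {
  cfg <- sim_config(duration_s = 520, noise_sd_ms = 2, p_ectopic = 0)
  wins <- 0
  for (k in 1:10) {
    sup <- compute_hrv(select_segment(clean_to_nn(
      generate_rr_series(cfg, condition = "supine", seed = 3000 + k))))
    stn <- compute_hrv(select_segment(clean_to_nn(
      generate_rr_series(cfg, condition = "standing", seed = 3000 + k))))
    if (stn$lf_nu > sup$lf_nu) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
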