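fake_indexes <- function(sdnn = 40, pnn50 = 10) {
  out <- setNames(as.list(rep(1, length(hrv_index_names()))),
                  hrv_index_names())
  out$sdnn_ms <- sdnn
  out$pnn50_pct <- pnn50
  out
}

test_that("deltas follow the maneuver-minus-supine convention", {
  ds <- compute_deltas(list(supine = fake_indexes(sdnn = 40),
                            breathing = fake_indexes(sdnn = 55)))
  expect_equal(unname(ds$delta_breathing["sdnn_ms"]), 15)
  expect_true(all(is.na(ds$delta_standing)))
  flipped <- compute_deltas(list(supine = fake_indexes(sdnn = 40),
                                 breathing = fake_indexes(sdnn = 55)),
                            sign_convention = "supine_minus_maneuver")
  expect_equal(unname(flipped$delta_breathing["sdnn_ms"]), -15)

  same <- compute_deltas(list(supine = fake_indexes(),
                              standing = fake_indexes(),
                              breathing = fake_indexes()))
  expect_true(all(same$delta_standing == 0))
  expect_true(all(same$delta_breathing == 0))
  expect_error(compute_deltas(list(standing = fake_indexes())), "supine")
})

test_that("missing values propagate as flagged missing deltas", {
  sup <- fake_indexes(); sup$log10_lf_hf <- NA_real_
  ds <- compute_deltas(list(supine = sup, standing = fake_indexes()))
  expect_true(is.na(ds$delta_standing["log10_lf_hf"]))
  expect_false(anyNA(ds$delta_standing[c("sdnn_ms", "sd1_ms")]))
})

test_that("ROC handles perfect separation and uninformative scores", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$auc, 1)
  expect_identical(rc$direction, "positive_if_le")
  expect_true(any(rc$curve$fpr == 0 & rc$curve$tpr == 1))
  bc <- best_cutoff(rc)
  expect_equal(bc$distance, 0)
  expect_equal(bc$sensitivity_pct, 100)
  expect_equal(bc$specificity_pct, 100)

  flat <- roc_curve(rep(5, 8), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                                 TRUE, FALSE))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoidal AUC equals tie-corrected pair counting exactly", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    scores <- sample(round(rnorm(n, 0, 2), 1))  # rounding forces ties
    labels <- sample(c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2,
                                           replace = TRUE)))
    for (dir in c("positive_if_le", "positive_if_ge")) {
      rc <- roc_curve(scores, labels, direction = dir)
      expect_equal(rc$auc, oracle_auc(scores, labels, dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(9)
  for (rep in 1:20) {
    scores <- rnorm(30)
    labels <- rbinom(30, 1, 0.4) == 1
    if (length(unique(labels)) < 2) next
    rc <- roc_curve(scores, labels, direction = "positive_if_ge")
    ref <- suppressMessages(pROC::roc(response = labels, predictor = scores,
                                      direction = "<", quiet = TRUE))
    expect_equal(rc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms; label swap flips it", {
  set.seed(12)
  scores <- rnorm(25)
  labels <- rbinom(25, 1, 0.5) == 1
  labels[1:2] <- c(TRUE, FALSE)
  a <- roc_curve(scores, labels, direction = "positive_if_ge")$auc
  b <- roc_curve(exp(scores), labels, direction = "positive_if_ge")$auc
  expect_equal(a, b, tolerance = 1e-12)
  swapped <- roc_curve(scores, !labels, direction = "positive_if_ge")$auc
  expect_equal(swapped, 1 - a, tolerance = 1e-12)
})

test_that("curve endpoints and monotonicity invariants hold", {
  set.seed(3)
  for (rep in 1:25) {
    scores <- round(rnorm(15), 1)
    labels <- c(TRUE, FALSE, rbinom(13, 1, 0.5) == 1)
    rc <- roc_curve(scores, labels)
    cv <- rc$curve
    expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_gte(rc$auc, 0.5)  # auto orientation
    bc <- best_cutoff(rc)
    hit <- abs(cv$tpr - bc$sensitivity_pct / 100) < 1e-12 &
      abs(1 - cv$fpr - bc$specificity_pct / 100) < 1e-12
    expect_true(any(hit))  # chosen operating point lies on the curve
  }
})

test_that("cut-off rule reproduces hand-enumerated distances on a toy curve", {
  toy <- structure(list(curve = data.frame(threshold = c(-Inf, -1, 0, 1),
                                           fpr = c(0, 0.2, 0.4, 1),
                                           tpr = c(0, 0.6, 0.9, 1)),
                        auc = 0.8, direction = "positive_if_le",
                        n_case = 10, n_control = 10),
                   class = "roc_result")
  bc <- best_cutoff(toy)
  expect_equal(bc$best_cutoff, 0)  # point (0.4, 0.9), distance sqrt(0.17)
  expect_equal(bc$sensitivity_pct, 90)
  expect_equal(bc$specificity_pct, 60)
  expect_equal(bc$distance, sqrt(0.17), tolerance = 1e-12)
  expect_match(bc$cutoff_label, "<=")

  tie <- toy
  # (0.25, 0.5) and (0.5, 0.75) are both at distance sqrt(0.3125) from
  # (0, 1); the coordinates are exact binary fractions so the tie is exact
  tie$curve <- data.frame(threshold = c(-Inf, -2, 2, 5),
                          fpr = c(0, 0.25, 0.5, 1),
                          tpr = c(0, 0.5, 0.75, 1))
  b1 <- best_cutoff(tie)
  expect_equal(b1$best_cutoff, -2)  # earliest threshold wins the tie
})

test_that("Hanley-McNeil inference behaves at the null and the boundary", {
  half <- auc_inference(0.5, n_case = 10, n_control = 12)
  expect_equal(half$p_value_vs_half, 1)
  one <- auc_inference(1, n_case = 8, n_control = 42)
  expect_equal(one$se, 0)
  expect_equal(one$auc_ci95, c(1, 1))
  expect_equal(one$p_value_vs_half, 0)
  expect_true(one$boundary)
  expect_error(auc_inference(0.7, n_case = 1, n_control = 10), "n_case")
})

test_that("roc_table covers every index-maneuver pair", {
  set.seed(5)
  cfg <- sim_config(n_subjects = 12, p_cardiotox = 0.5, seed = 31,
                    lambda_reactivity = 0.3, duration_s = 600)
  dt <- cohort_delta_table(generate_cohort(cfg))
  rt <- roc_table(dt)
  expect_equal(nrow(rt), length(hrv_index_names()) * 2)
  expect_true(all(rt$auc >= 0.5 & rt$auc <= 1, na.rm = TRUE))
  expect_true(all(rt$sensitivity_pct >= 0 & rt$sensitivity_pct <= 100,
                  na.rm = TRUE))
})
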