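#' Normality-gated log10 transform
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with
#' the sample mean and SD; when it rejects (p < 0.05) the values are
#' log10-transformed. The KS p-value with estimated parameters is known to
#' be conservative (no Lilliefors correction is applied); the uncorrected
#' version mirrors common clinical-statistics practice.
#'
#' @param values numeric vector, n >= 5.
#' @param alpha gate significance level.
#' @return list: `values` (possibly transformed), `was_transformed`,
#'   `ks_p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: zero variance, KS test undefined")
  p <- suppressWarnings(ks.test(values, "pnorm", mean(values), s)$p.value)
  if (p < alpha) {
    if (any(values <= 0))
      stop("log10 transform triggered but values are not all positive; ",
           "decide on an offset or exclusion upstream")
    list(values = log10(values), was_transformed = TRUE, ks_p = p)
  } else {
    list(values = values, was_transformed = FALSE, ks_p = p)
  }
}

#' Two-group comparison by Student's t-test
#'
#' Pooled-variance t-test for independent groups, difference-score t-test
#' for paired data; summaries as mean and SD per group.
#'
#' @param values_a,values_b numeric vectors (equal length when paired).
#' @param paired logical.
#' @return list: `statistic`, `df`, `p_value`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `paired`. The statistic and p are `NA` (flagged, not an
#'   error) when the test is degenerate (zero variance everywhere).
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths")
  out <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              mean_a = mean(a), sd_a = sd(a),
              mean_b = mean(b), sd_b = sd(b), paired = paired)
  degenerate <- if (paired) sd(a - b) == 0 else (sd(a) == 0 && sd(b) == 0)
  if (degenerate) {
    if (paired && all(a == b)) {
      out$statistic <- 0; out$p_value <- 1; out$df <- length(a) - 1
    }
    return(out)
  }
  tt <- if (paired) t.test(a, b, paired = TRUE)
        else t.test(a, b, var.equal = TRUE)
  out$statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}

#' One-way repeated-measures ANOVA across conditions
#'
#' Subject-blocked one-way ANOVA: condition F tested against the
#' subject-by-condition residual with (k - 1, (k - 1)(n - 1)) degrees of
#' freedom. No sphericity correction is applied.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns;
#'   complete (no missing cells).
#' @return list: `F`, `df1`, `df2`, `p_value`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 conditions")
  if (any(!is.finite(values))) stop("missing cells are not allowed")
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), k)),
                   condition = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(y ~ condition + subject, data = df))[[1]]
  ss <- tab[, "Sum Sq"]
  names(ss) <- trimws(rownames(tab))
  scale <- max(sum(ss), 1)
  Fv <- if (ss[["condition"]] <= 1e-12 * scale) 0
        else if (ss[["Residuals"]] <= 1e-12 * scale) Inf
        else tab["condition", "F value"]
  p <- pf_upper(Fv, k - 1, (k - 1) * (n - 1))
  list(F = Fv, df1 = k - 1, df2 = (k - 1) * (n - 1), p_value = p)
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Chi-squared or Fisher's exact test on a 2x2 table
#'
#' Chi-squared without continuity correction when every expected count is
#' at least 5; otherwise Fisher's exact test (two-sided, summing the
#' probabilities of tables as extreme or more).
#'
#' @param table_2x2 2x2 matrix of nonnegative integer counts.
#' @return list: `statistic` (chi-squared value, `NA` for Fisher),
#'   `p_value`, `method_used` (`"chisq"` or `"fisher"`), `expected`.
#' @export
categorical_test <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero-margin table: test undefined")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         method_used = "chisq", expected = expected)
  } else {
    ft <- fisher.test(m)
    list(statistic = NA_real_, p_value = ft$p.value,
         method_used = "fisher", expected = expected)
  }
}

#' Pearson correlation panel between echo and HRV variables
#'
#' Pairwise Pearson r with two-sided t-based p-values, echo variables in
#' rows and HRV variables in columns; p-values are unadjusted (no
#' multiplicity correction is applied, but the number of tests performed
#' is reported so readers can judge). Pairs with fewer than 4 complete
#' observations or zero variance are flagged `NA`.
#'
#' @param echo_fields data.frame (or named list) of echo variables.
#' @param hrv_fields data.frame of HRV variables on the same subjects.
#' @return list: `r` and `p` matrices (echo x HRV), `n` matrix of pairwise
#'   complete counts, `n_tests`.
#' @export
pearson_matrix <- function(echo_fields, hrv_fields) {
  e <- as.data.frame(echo_fields); h <- as.data.frame(hrv_fields)
  if (nrow(e) != nrow(h)) stop("echo and HRV tables must align by subject")
  r <- p <- nmat <- matrix(NA_real_, ncol(e), ncol(h),
                           dimnames = list(names(e), names(h)))
  n_tests <- 0
  for (i in seq_len(ncol(e))) for (j in seq_len(ncol(h))) {
    ok <- complete.cases(e[[i]], h[[j]])
    nmat[i, j] <- sum(ok)
    if (sum(ok) >= 4 && sd(e[[i]][ok]) > 0 && sd(h[[j]][ok]) > 0) {
      ct <- cor.test(e[[i]][ok], h[[j]][ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
      n_tests <- n_tests + 1
    }
  }
  list(r = r, p = p, n = nmat, n_tests = n_tests)
}

#' Significant left-atrial reservoir strain reduction
#'
#' A follow-up LASr is a significant reduction when the baseline was at or
#' above the 35% normal threshold and the follow-up either falls below
#' that threshold or drops by more than 10% relative to baseline. When the
#' baseline is already below 35%, only a > 10% relative reduction counts.
#'
#' @param lasr_baseline_pct,lasr_followup_pct LASr values in percent (> 0).
#' @param normal_threshold_pct,relative_reduction threshold parameters.
#' @return logical.
#' @export
las_significant_reduction <- function(lasr_baseline_pct, lasr_followup_pct,
                                      normal_threshold_pct = 35,
                                      relative_reduction = 0.10) {
  b <- lasr_baseline_pct; f <- lasr_followup_pct
  if (any(!is.finite(c(b, f))) || b <= 0 || f <= 0)
    stop("LASr values must be positive")
  rel <- (b - f) / b
  if (b >= normal_threshold_pct)
    f < normal_threshold_pct || rel > relative_reduction
  else
    rel > relative_reduction
}

#' Cardiotoxicity criteria configuration
#'
#' @param lvef_threshold_pct follow-up LVEF below this, and
#' @param lvef_drop_pct with an absolute drop of at least this many
#'   points, satisfies the LVEF arm of the echo criterion.
#' @param gls_relative_reduction relative reduction of |GLS| beyond which
#'   the strain arm of the echo criterion is satisfied.
#' @return list of class `ctox_criteria`.
#' @export
ctox_criteria <- function(lvef_threshold_pct = 53, lvef_drop_pct = 10,
                          gls_relative_reduction = 0.10) {
  structure(list(lvef_threshold_pct = lvef_threshold_pct,
                 lvef_drop_pct = lvef_drop_pct,
                 gls_relative_reduction = gls_relative_reduction),
            class = "ctox_criteria")
}

#' Classify a subject's cardiotoxicity status
#'
#' Echo criterion (default): follow-up LVEF below 53% with an absolute
#' drop of at least 10 points, or a relative reduction of GLS magnitude
#' greater than 10% (|GLS| shrinking toward zero is function loss).
#' Troponin criterion: conversion from a negative baseline to a positive
#' follow-up. The label combines the two.
#'
#' @param echo_baseline,echo_followup echo panels (named lists with at
#'   least `lvef3d_pct` and `gls_pct`).
#' @param troponin named logical vector with `baseline` and `followup`
#'   entries.
#' @param criteria a [ctox_criteria()].
#' @return list: `label` in `{"echo", "troponin", "both", "none"}`,
#'   `echo_criterion`, `troponin_criterion`.
#' @export
classify_cardiotoxicity <- function(echo_baseline, echo_followup, troponin,
                                    criteria = ctox_criteria()) {
  if (is.null(echo_followup) || is.null(echo_followup$lvef3d_pct))
    stop("unclassifiable: follow-up echo missing")
  lvef_b <- echo_baseline$lvef3d_pct; lvef_f <- echo_followup$lvef3d_pct
  gls_b <- abs(echo_baseline$gls_pct); gls_f <- abs(echo_followup$gls_pct)
  lvef_hit <- lvef_f < criteria$lvef_threshold_pct &&
    (lvef_b - lvef_f) >= criteria$lvef_drop_pct
  gls_hit <- gls_b > 0 && (gls_b - gls_f) / gls_b > criteria$gls_relative_reduction
  echo_crit <- isTRUE(lvef_hit) || isTRUE(gls_hit)
  tro_crit <- isTRUE(troponin[["followup"]]) && !isTRUE(troponin[["baseline"]])
  label <- if (echo_crit && tro_crit) "both"
           else if (echo_crit) "echo"
           else if (tro_crit) "troponin"
           else "none"
  list(label = label, echo_criterion = echo_crit, troponin_criterion = tro_crit)
}
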