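#' Empirical ROC curve for a reactivity index
#'
#' Sweeps every distinct score as a decision threshold under both
#' orientations (case-positive when the score is at most, or at least, the
#' threshold), keeps the orientation whose area under the curve is >= 0.5,
#' and reports the curve, the trapezoidal AUC and the orientation. Tied
#' scores collapse into a single threshold step, so ties contribute
#' diagonal segments and the trapezoidal AUC equals the tie-corrected
#' Mann-Whitney pair count.
#'
#' @param scores numeric vector of per-subject delta values (finite).
#' @param labels logical (or 0/1) vector: `TRUE` for cardiotoxicity cases.
#' @param direction `"auto"` (default, AUC-maximizing), `"positive_if_le"`
#'   or `"positive_if_ge"`.
#' @return list of class `roc_result`: `curve` (data.frame `threshold`,
#'   `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `direction`, `n_case`,
#'   `n_control`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("auto", "positive_if_le",
                                    "positive_if_ge")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("ROC undefined: both classes must be present")
  build <- function(dir) {
    thr <- sort(unique(scores), decreasing = (dir == "positive_if_ge"))
    pos <- if (dir == "positive_if_ge")
      function(c) scores >= c else function(c) scores <= c
    tpr <- vapply(thr, function(c) sum(pos(c) & labels) / n1, 0)
    fpr <- vapply(thr, function(c) sum(pos(c) & !labels) / n0, 0)
    curve <- data.frame(threshold = c(if (dir == "positive_if_ge") Inf else -Inf,
                                      thr),
                        fpr = c(0, fpr), tpr = c(0, tpr))
    auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
    list(curve = curve, auc = auc, direction = dir)
  }
  res <- if (direction == "auto") {
    ge <- build("positive_if_ge")
    if (ge$auc >= 0.5) ge else build("positive_if_le")
  } else build(direction)
  structure(c(res, list(n_case = n1, n_control = n0)), class = "roc_result")
}

#' Best cut-off by distance to the ideal classifier
#'
#' Selects the curve point with the shortest Euclidean distance to the
#' optimum (0, 1) -- perfect sensitivity and specificity -- and reports the
#' corresponding threshold with its direction symbol. Ties go to the most
#' extreme threshold (the earliest point along the sweep).
#'
#' @param result a [roc_curve()] result.
#' @return list: `best_cutoff`, `direction`, `cutoff_label` (e.g.
#'   `"<= -8.44"`), `sensitivity_pct`, `specificity_pct`,
#'   `distance` (achieved distance to (0,1)).
#' @export
best_cutoff <- function(result) {
  stopifnot(inherits(result, "roc_result"))
  cv <- result$curve
  if (nrow(cv) == 0) stop("empty ROC curve")
  d <- sqrt((1 - cv$tpr)^2 + cv$fpr^2)
  i <- which.min(d)  # earliest on ties
  sym <- if (result$direction == "positive_if_le") "<=" else ">="
  list(best_cutoff = cv$threshold[i],
       direction = result$direction,
       cutoff_label = sprintf("%s %.4g", sym, cv$threshold[i]),
       sensitivity_pct = 100 * cv$tpr[i],
       specificity_pct = 100 * (1 - cv$fpr[i]),
       distance = d[i])
}

#' AUC confidence interval and test against 0.5
#'
#' Standard error by the Hanley-McNeil formula; the 95% confidence
#' interval is `auc +/- 1.96 SE` truncated to \[0, 1\] and the p-value is
#' the two-sided normal test of the null AUC = 0.5. A degenerate SE of 0
#' away from 0.5 (perfect separation) is flagged as a boundary case.
#'
#' @param result a [roc_curve()] result (or a bare AUC value).
#' @param n_case,n_control class sizes; taken from `result` when omitted.
#' @return list: `auc`, `se`, `auc_ci95` (length-2), `p_value_vs_half`,
#'   `boundary` flag.
#' @export
auc_inference <- function(result, n_case = NULL, n_control = NULL) {
  if (inherits(result, "roc_result")) {
    auc <- result$auc
    n_case <- n_case %||% result$n_case
    n_control <- n_control %||% result$n_control
  } else auc <- as.numeric(result)
  if (is.null(n_case) || is.null(n_control) || n_case < 2 || n_control < 2)
    stop("need n_case and n_control >= 2")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se2 <- (auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
            (n_control - 1) * (q2 - auc^2)) / (n_case * n_control)
  se <- sqrt(max(se2, 0))
  boundary <- se == 0 && auc != 0.5
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se)
       else if (auc == 0.5) 1 else 0
  list(auc = auc, se = se,
       auc_ci95 = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
       p_value_vs_half = p, boundary = boundary)
}

#' ROC summary table over all reactivity indexes
#'
#' Builds the per-index, per-maneuver ROC summary (AUC with CI and p-value
#' against 0.5, cut-off with direction symbol, sensitivity, specificity)
#' from a [cohort_delta_table()].
#'
#' @param deltas data.frame from [cohort_delta_table()] (columns
#'   `subject_id`, `group`, `maneuver`, one column per index).
#' @param case_group value of `group` treated as positive.
#' @return data.frame, one row per (index, maneuver) with columns `index`,
#'   `maneuver`, `n_case`, `n_control`, `auc`, `ci_low`, `ci_high`,
#'   `p_value`, `cutoff`, `cutoff_label`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
roc_table <- function(deltas, case_group = "cardiotox") {
  idx_cols <- intersect(hrv_index_names(), names(deltas))
  rows <- list()
  for (m in unique(deltas$maneuver)) {
    sub <- deltas[deltas$maneuver == m, ]
    for (f in idx_cols) {
      sc <- sub[[f]]
      lb <- sub$group == case_group
      ok <- is.finite(sc)
      row <- data.frame(index = f, maneuver = m,
                        n_case = sum(lb & ok), n_control = sum(!lb & ok),
                        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, cutoff = NA_real_,
                        cutoff_label = NA_character_,
                        sensitivity_pct = NA_real_,
                        specificity_pct = NA_real_)
      if (row$n_case >= 2 && row$n_control >= 2) {
        rc <- roc_curve(sc[ok], lb[ok])
        bc <- best_cutoff(rc)
        inf <- auc_inference(rc)
        row$auc <- rc$auc
        row$ci_low <- inf$auc_ci95[1]; row$ci_high <- inf$auc_ci95[2]
        row$p_value <- inf$p_value_vs_half
        row$cutoff <- bc$best_cutoff
        row$cutoff_label <- bc$cutoff_label
        row$sensitivity_pct <- bc$sensitivity_pct
        row$specificity_pct <- bc$specificity_pct
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
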