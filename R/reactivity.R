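#' Reactivity deltas for one subject
#'
#' The autonomic reactivity of an index is its change between supine rest
#' and a maneuver. The default sign convention is maneuver minus supine, so
#' an index that rises during the maneuver gives a positive delta and a
#' blunted response gives a smaller (possibly negative) one; the opposite
#' convention is available for compatibility with supine-minus-maneuver
#' reporting.
#'
#' @param indexes named list mapping condition (`"supine"` plus at least
#'   one of `"standing"`, `"breathing"`) to an [compute_hrv()] result or a
#'   named list of index values.
#' @param sign_convention `"maneuver_minus_supine"` (default) or
#'   `"supine_minus_maneuver"`.
#' @return list of class `delta_set` with `delta_standing` and
#'   `delta_breathing` (named numeric vectors over the index fields; all
#'   `NA` when that maneuver is absent, per-index `NA` when either value is
#'   missing).
#' @export
compute_deltas <- function(indexes,
                           sign_convention = c("maneuver_minus_supine",
                                               "supine_minus_maneuver")) {
  sign_convention <- match.arg(sign_convention)
  if (is.null(indexes$supine)) stop("supine indexes are required")
  if (is.null(indexes$standing) && is.null(indexes$breathing))
    stop("at least one maneuver (standing or breathing) is required")
  fields <- intersect(hrv_index_names(), names(indexes$supine))
  one <- function(maneuver) {
    out <- setNames(rep(NA_real_, length(fields)), fields)
    m <- indexes[[maneuver]]
    if (!is.null(m)) {
      for (f in fields) {
        a <- indexes$supine[[f]]; b <- m[[f]]
        if (!is.null(a) && !is.null(b) && is.finite(a) && is.finite(b))
          out[f] <- if (sign_convention == "maneuver_minus_supine")
            b - a else a - b
      }
    }
    out
  }
  structure(list(delta_standing = one("standing"),
                 delta_breathing = one("breathing"),
                 sign_convention = sign_convention),
            class = "delta_set")
}

#' Per-subject delta table for a cohort
#'
#' Runs the full per-subject chain -- NN cleaning, stable-segment
#' selection, index computation, reactivity deltas -- over every subject of
#' a synthetic (or assembled) cohort at one timepoint and returns a tidy
#' table of deltas alongside the group labels.
#'
#' @param cohort a [generate_cohort()] result.
#' @param timepoint `"baseline"` or `"followup"`.
#' @param indexes character vector of index fields to compute; restricting
#'   to time-domain/Poincare fields skips the spectral stage.
#' @param maneuvers which maneuvers to process.
#' @param L,skip_s segment selection parameters, see [select_segment()].
#' @param settings an [hrv_settings()].
#' @param filter_config an [nn_filter_config()].
#' @return data.frame with `subject_id`, `group`, `maneuver`, and one
#'   column per requested index holding the delta values.
#' @export
cohort_delta_table <- function(cohort, timepoint = "baseline",
                               indexes = hrv_index_names(),
                               maneuvers = c("standing", "breathing"),
                               L = 300, skip_s = 180,
                               settings = hrv_settings(),
                               filter_config = nn_filter_config()) {
  indexes <- match.arg(indexes, hrv_index_names(), several.ok = TRUE)
  maneuvers <- match.arg(maneuvers, c("standing", "breathing"),
                         several.ok = TRUE)
  spectral <- any(indexes %in% c("lf_power_ms2", "hf_power_ms2", "lf_nu",
                                 "hf_nu", "log10_lf_hf"))
  one_condition <- function(subject, cond) {
    rec <- subject$recordings[[paste(timepoint, cond, sep = ".")]]
    if (is.null(rec)) return(NULL)
    seg <- select_segment(clean_to_nn(rec, filter_config), L = L,
                          skip_s = skip_s)
    if (spectral) compute_hrv(seg, settings)
    else c(time_domain(seg), poincare(seg))
  }
  rows <- lapply(cohort, function(s) {
    vals <- list(supine = one_condition(s, "supine"))
    for (m in maneuvers) vals[[m]] <- one_condition(s, m)
    ds <- compute_deltas(vals)
    do.call(rbind, lapply(maneuvers, function(m) {
      d <- ds[[paste0("delta_", m)]][indexes]
      cbind(data.frame(subject_id = s$subject_id, group = s$group,
                       maneuver = m), as.data.frame(as.list(d)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
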