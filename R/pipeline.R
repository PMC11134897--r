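#' Read a cohort directory written by [write_cohort()]
#'
#' Reconstructs per-subject recordings from `<id>_<timepoint>_<condition>.rr`
#' tachogram files, and group labels / echo panels / troponin flags from
#' `cohort.csv` when present.
#'
#' @param dir directory path.
#' @return A `synthetic_cohort`-shaped list (recordings possibly
#'   incomplete; missing conditions are simply absent).
#' @export
read_cohort_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.rr$", full.names = TRUE)
  if (!length(files)) stop("no .rr tachogram files in ", dir)
  meta <- regmatches(basename(files),
                     regexec("^(.+)_(baseline|followup)_(supine|standing|breathing)\\.rr$",
                             basename(files)))
  subjects <- list()
  for (i in seq_along(files)) {
    m <- meta[[i]]
    if (length(m) != 4) next
    id <- m[2]
    if (is.null(subjects[[id]]))
      subjects[[id]] <- structure(
        list(subject_id = id, group = NA_character_, recordings = list(),
             echo = NULL, troponin_positive = NULL),
        class = "synthetic_subject")
    subjects[[id]]$recordings[[paste(m[3], m[4], sep = ".")]] <-
      read_tachogram(files[i], condition = m[4], timepoint = m[3],
                     subject_id = id)
  }
  csv <- file.path(dir, "cohort.csv")
  if (file.exists(csv)) {
    tab <- read.csv(csv, stringsAsFactors = FALSE)
    pop <- echo_population()$field
    for (r in seq_len(nrow(tab))) {
      id <- tab$subject_id[r]
      if (is.null(subjects[[id]])) next
      subjects[[id]]$group <- tab$group[r]
      subjects[[id]]$echo <- lapply(
        setNames(.timepoints, .timepoints),
        function(tp) {
          cols <- paste0(pop, "_", tp)
          if (all(cols %in% names(tab)))
            setNames(as.list(as.numeric(tab[r, cols])), pop)
        })
      subjects[[id]]$troponin_positive <-
        c(baseline = isTRUE(tab$troponin_baseline[r]),
          followup = isTRUE(tab$troponin_followup[r]))
    }
  }
  structure(unname(subjects), class = "synthetic_cohort")
}

#' Validate a tachogram input directory
#'
#' Checks the tachogram dialect (parsable numeric intervals), interval
#' positivity, and subject-level completeness of the timepoint-by-condition
#' grid. Problems are reported, not thrown.
#'
#' @param dir directory path.
#' @return data.frame with columns `defect`, `file`, `detail`; zero rows
#'   when the directory is clean.
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  defects <- list()
  add <- function(defect, file, detail)
    defects[[length(defects) + 1]] <<- data.frame(defect = defect,
                                                  file = file, detail = detail)
  files <- list.files(dir, pattern = "\\.rr$", full.names = TRUE)
  seen <- list()
  for (f in files) {
    lines <- tryCatch(readLines(f), error = function(e) NULL)
    if (is.null(lines)) { add("unreadable", basename(f), ""); next }
    dat_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
    iv <- suppressWarnings(as.numeric(vapply(
      strsplit(trimws(lines[dat_idx]), "\\s+"), `[`, "", 1)))
    bad <- which(is.na(iv))
    for (b in bad) add("non-numeric interval", basename(f),
                       sprintf("line %d", dat_idx[b]))
    neg <- which(!is.na(iv) & iv <= 0)
    for (b in neg) add("non-positive interval", basename(f),
                       sprintf("line %d: %g", dat_idx[b], iv[b]))
    m <- regexec("^(.+)_(baseline|followup)_(supine|standing|breathing)\\.rr$",
                 basename(f))[[1]]
    if (length(m)) {
      parts <- regmatches(basename(f), list(m))[[1]]
      seen[[parts[2]]] <- c(seen[[parts[2]]], paste(parts[3], parts[4], sep = "."))
    } else add("unrecognized file name", basename(f), "")
  }
  full <- as.vector(outer(.timepoints, .conditions, paste, sep = "."))
  for (id in names(seen)) {
    missing <- setdiff(full, seen[[id]])
    for (mi in missing)
      add("incomplete recordings", id, sprintf("missing %s", mi))
  }
  if (!length(defects))
    return(data.frame(defect = character(), file = character(),
                      detail = character()))
  out <- do.call(rbind, defects)
  rownames(out) <- NULL
  out
}

index_table <- function(cohort, L, skip_s, settings, filter_config,
                        warn = function(...) invisible()) {
  rows <- list()
  for (s in cohort) {
    for (key in names(s$recordings)) {
      rec <- s$recordings[[key]]
      res <- tryCatch({
        seg <- select_segment(clean_to_nn(rec, filter_config), L, skip_s)
        compute_hrv(seg, settings)
      }, error = function(e) { warn(conditionMessage(e)); NULL })
      row <- data.frame(subject_id = s$subject_id, group = s$group,
                        timepoint = rec$timepoint, condition = rec$condition)
      for (f in hrv_index_names())
        row[[f]] <- if (is.null(res)) NA_real_ else res[[f]]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

delta_table_from_indexes <- function(indexes) {
  rows <- list()
  for (id in unique(indexes$subject_id)) {
    for (tp in unique(indexes$timepoint)) {
      sub <- indexes[indexes$subject_id == id & indexes$timepoint == tp, ]
      get <- function(cond) {
        r <- sub[sub$condition == cond, ]
        if (nrow(r) != 1) return(NULL)
        as.list(r[1, hrv_index_names()])
      }
      sup <- get("supine")
      if (is.null(sup)) next
      vals <- list(supine = sup, standing = get("standing"),
                   breathing = get("breathing"))
      if (is.null(vals$standing) && is.null(vals$breathing)) next
      ds <- compute_deltas(vals)
      for (m in c("standing", "breathing")) {
        row <- data.frame(subject_id = id, group = sub$group[1],
                          timepoint = tp, maneuver = m)
        d <- ds[[paste0("delta_", m)]]
        for (f in hrv_index_names()) row[[f]] <- unname(d[f])
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

condition_summary <- function(indexes) {
  agg <- list()
  for (tp in unique(indexes$timepoint))
    for (cond in unique(indexes$condition)) {
      sub <- indexes[indexes$timepoint == tp & indexes$condition == cond, ]
      for (f in hrv_index_names()) {
        v <- sub[[f]][is.finite(sub[[f]])]
        agg[[length(agg) + 1]] <- data.frame(
          timepoint = tp, condition = cond, index = f, n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1) sd(v) else NA_real_)
      }
    }
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

group_delta_comparison <- function(deltas, case_group = "cardiotox") {
  rows <- list()
  for (tp in unique(deltas$timepoint)) for (m in unique(deltas$maneuver)) {
    sub <- deltas[deltas$timepoint == tp & deltas$maneuver == m, ]
    for (f in hrv_index_names()) {
      a <- sub[[f]][sub$group == case_group & is.finite(sub[[f]])]
      b <- sub[[f]][sub$group != case_group & is.finite(sub[[f]])]
      if (length(a) < 2 || length(b) < 2) next
      cg <- compare_groups(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = tp, maneuver = m, index = f,
        n_case = length(a), n_control = length(b),
        mean_case = cg$mean_a, sd_case = cg$sd_a,
        mean_control = cg$mean_b, sd_control = cg$sd_b,
        t = cg$statistic, p_value = cg$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full reactivity pipeline
#'
#' Orchestrates simulate (or load) -> validate -> preprocess -> indexes ->
#' deltas -> ROC -> cohort statistics, writing one CSV per stage plus a
#' JSON run manifest with configuration, seed, package version, per-file
#' MD5 digests and collected warnings. Identical configuration and seed
#' give identical digests.
#'
#' @param config a named list, a YAML file path, or `NULL` for defaults.
#'   Recognized entries: `sim` (fields for [sim_config()]), `input_dir`
#'   (read tachograms instead of simulating), `L`, `skip_s`, filter
#'   settings (`median_window`, `threshold`), spectral settings
#'   (`resample_hz`, `welch_window`, `overlap`), `case_group`.
#' @param out_dir output directory.
#' @param seed overrides `sim$seed` when given.
#' @return The manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("hrvrun"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- yaml::read_yaml(config)
  config <- config %||% list()
  sim_args <- config$sim %||% list()
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  warnings_log <- character()
  warn <- function(msg) warnings_log <<- c(warnings_log, msg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "simulate"
  result <- tryCatch({
    cohort <- if (!is.null(config$input_dir)) {
      stage <- "load"
      read_cohort_dir(config$input_dir)
    } else {
      cfg <- do.call(sim_config, sim_args)
      generate_cohort(cfg)
    }
    L <- config$L %||% 300
    skip_s <- config$skip_s %||% 180
    fc <- nn_filter_config(median_window = config$median_window %||% 11,
                           threshold = config$threshold %||% 0.20)
    st <- hrv_settings(resample_hz = config$resample_hz %||% 3,
                       window_len = config$welch_window %||% 256,
                       overlap = config$overlap %||% 0.5)
    case_group <- config$case_group %||% "cardiotox"

    stage <- "indexes"
    indexes <- index_table(cohort, L, skip_s, st, fc, warn)
    stage <- "deltas"
    deltas <- delta_table_from_indexes(indexes)
    stage <- "roc"
    roc <- roc_table(deltas[deltas$timepoint == "baseline", ], case_group)
    stage <- "stats"
    summary_tab <- condition_summary(indexes)
    group_tab <- group_delta_comparison(deltas, case_group)
    cls <- do.call(rbind, lapply(cohort, function(s) {
      lab <- tryCatch(classify_cardiotoxicity(s$echo$baseline,
                                              s$echo$followup,
                                              s$troponin_positive)$label,
                      error = function(e) { warn(conditionMessage(e));
                                            NA_character_ })
      data.frame(subject_id = s$subject_id, group = s$group,
                 classified = lab)
    }))
    list(indexes = indexes, deltas = deltas, roc = roc,
         summary = summary_tab, groups = group_tab, classification = cls)
  }, error = function(e) {
    dir.create(file.path(out_dir, "failed"), showWarnings = FALSE)
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "failed", "MARKER"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- c(indexes = "indexes.csv", deltas = "deltas.csv",
             roc = "roc_table.csv", summary = "condition_summary.csv",
             groups = "group_comparison.csv",
             classification = "classification.csv")
  for (nm in names(files))
    write.csv(result[[nm]], file.path(out_dir, files[nm]), row.names = FALSE)
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest <- structure(
    list(config = config, seed = sim_args$seed,
         version = as.character(packageVersion("hrvreact")),
         files = setNames(unname(digests), unname(files)),
         warnings = warnings_log, tables = result),
    class = "run_manifest")
  mj <- manifest[c("config", "seed", "version", "files", "warnings")]
  writeLines(format_manifest_json(mj), file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# minimal JSON writer for the manifest (flat values, named lists, vectors)
format_manifest_json <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  fmt <- function(v, ind) {
    if (is.null(v)) return("null")
    if (!is.list(v) && length(v) == 0) return("[]")
    if (is.list(v)) {
      if (length(v) == 0) return("{}")
      keys <- names(v) %||% rep("", length(v))
      inner <- vapply(seq_along(v), function(i)
        sprintf('%s  "%s": %s', ind, esc(keys[i]),
                fmt(v[[i]], paste0(ind, "  "))), "")
      return(sprintf("{\n%s\n%s}", paste(inner, collapse = ",\n"), ind))
    }
    if (length(v) > 1) {
      if (!is.null(names(v)))
        return(fmt(as.list(v), ind))
      return(sprintf("[%s]", paste(vapply(v, fmt, "", ind), collapse = ", ")))
    }
    if (is.character(v)) return(sprintf('"%s"', esc(v)))
    if (is.logical(v)) return(if (isTRUE(v)) "true" else "false")
    format(v, digits = 15)
  }
  fmt(x, indent)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> hrvreact %s, seed %s\n", x$version,
              x$seed %||% "default"))
  cat(sprintf("  %d output files, %d warnings\n", length(x$files),
              length(x$warnings)))
  invisible(x)
}
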