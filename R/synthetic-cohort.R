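#' Simulation configuration for the synthetic cohort generator
#'
#' Defines the generative law for a fully synthetic study cohort: ~10-minute
#' RR recordings per condition (supine, active standing, paced breathing)
#' at two timepoints, an echocardiographic panel per timepoint, and troponin
#' flags. RR series come from a modulated point process with an LF
#' (baroreflex, 0.1 Hz) and a respiratory component; condition effects shift
#' mean RR and the two amplitudes. Subjects in the cardiotoxicity arm have
#' their condition-induced parameter changes attenuated by
#' `lambda_reactivity`, emulating blunted autonomic reactivity.
#'
#' Default amplitudes and jitter place supine SDNN in the 20-60 ms range
#' typical of short-term resting recordings in middle-aged adults.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param p_cardiotox probability a subject is assigned to the
#'   cardiotoxicity arm.
#' @param seed integer master seed; per-subject substreams are derived from
#'   it so subject k's data do not depend on `n_subjects`.
#' @param duration_s recording length per condition, seconds.
#' @param base_rr_ms population mean supine RR interval (ms), in [400, 1500].
#' @param a_lf,a_hf fractional modulation amplitudes of the LF and
#'   respiratory components, each in [0, 0.2].
#' @param f_resp_spont,f_resp_paced spontaneous and paced breathing rates, Hz.
#' @param standing_effect numeric triple `(rr_shorten, lf_gain, hf_loss)`:
#'   active standing multiplies mean RR by `1 - rr_shorten`, the LF
#'   amplitude by `lf_gain` (> 1) and the respiratory amplitude by
#'   `hf_loss` (< 1).
#' @param breathing_effect numeric pair `(paced_gain, total_gain)`: paced
#'   breathing moves the respiratory component to `f_resp_paced`,
#'   multiplies its amplitude by `paced_gain` and both amplitudes by
#'   `total_gain`.
#' @param lambda_reactivity attenuation in [0, 1] applied to condition
#'   effects in the cardiotoxicity arm; 1 reproduces the control law
#'   exactly, 0 abolishes reactivity.
#' @param p_ectopic per-beat probability of an ectopic (early beat plus
#'   compensatory pause).
#' @param noise_sd_ms white beat-to-beat jitter SD, ms.
#' @param subject_sd list of between-subject variability settings:
#'   `rr0_sd_ms` (SD of subject mean RR), `log_amp_sd` (SD of the
#'   log-normal multiplier shared by a subject's modulation amplitudes).
#' @param p_echo_effect probability a cardiotoxicity subject receives a
#'   follow-up strain shift large enough to satisfy the default
#'   echocardiographic criterion.
#' @param p_troponin_case,p_troponin_control probability of a positive
#'   follow-up troponin in each arm (baselines are negative).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 50,
                       p_cardiotox = 0.46,
                       seed = 20260101,
                       duration_s = 600,
                       base_rr_ms = 850,
                       a_lf = 0.03,
                       a_hf = 0.025,
                       f_resp_spont = 0.25,
                       f_resp_paced = 0.1,
                       standing_effect = c(rr_shorten = 0.12,
                                           lf_gain = 1.6, hf_loss = 0.5),
                       breathing_effect = c(paced_gain = 2.0,
                                            total_gain = 1.2),
                       lambda_reactivity = 1,
                       p_ectopic = 0.003,
                       noise_sd_ms = 5,
                       subject_sd = list(rr0_sd_ms = 60, log_amp_sd = 0.15),
                       p_echo_effect = 0.9,
                       p_troponin_case = 0.7,
                       p_troponin_control = 0.02) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              p_cardiotox = p_cardiotox, seed = as.integer(seed),
              duration_s = duration_s, base_rr_ms = base_rr_ms,
              a_lf = a_lf, a_hf = a_hf,
              f_resp_spont = f_resp_spont, f_resp_paced = f_resp_paced,
              standing_effect = standing_effect,
              breathing_effect = breathing_effect,
              lambda_reactivity = lambda_reactivity,
              p_ectopic = p_ectopic, noise_sd_ms = noise_sd_ms,
              subject_sd = subject_sd,
              p_echo_effect = p_echo_effect,
              p_troponin_case = p_troponin_case,
              p_troponin_control = p_troponin_control)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_cardiotox, cfg$p_ectopic, cfg$p_echo_effect,
             cfg$p_troponin_case, cfg$p_troponin_control)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  if (cfg$base_rr_ms < 400 || cfg$base_rr_ms > 1500)
    stop("base_rr_ms must lie in [400, 1500]")
  if (cfg$a_lf < 0 || cfg$a_lf > 0.2 || cfg$a_hf < 0 || cfg$a_hf > 0.2)
    stop("modulation amplitudes must lie in [0, 0.2]")
  if (cfg$lambda_reactivity < 0 || cfg$lambda_reactivity > 1)
    stop("lambda_reactivity must lie in [0, 1]")
  if (length(cfg$standing_effect) != 3 || length(cfg$breathing_effect) != 2)
    stop("standing_effect needs 3 values, breathing_effect 2")
  invisible(cfg)
}

# Deterministic substream seed for subject k: subject data are invariant to
# n_subjects because each subject reseeds from its own derived value.
subject_seed <- function(master_seed, k) {
  as.integer((as.double(master_seed) + 104729 * as.double(k)) %% 2147483647L)
}

# Effective modulation parameters for one condition, before attenuation.
# The respiratory frequency (and, under paced breathing, the phase lock of
# the respiratory component onto the 0.1 Hz baroreflex oscillation) is the
# mechanical part of the stimulus and applies to every subject; only the
# autonomically mediated amplitude and mean-RR responses are attenuated by
# lambda in the cardiotoxicity arm.
condition_params <- function(cfg, base, condition) {
  p <- base  # list(rr0, a_lf, a_hf, f_resp)
  if (condition == "standing") {
    p$rr0 <- base$rr0 * (1 - cfg$standing_effect[[1]])
    p$a_lf <- base$a_lf * cfg$standing_effect[[2]]
    p$a_hf <- base$a_hf * cfg$standing_effect[[3]]
  } else if (condition == "breathing") {
    p$f_resp <- cfg$f_resp_paced
    p$a_hf <- base$a_hf * cfg$breathing_effect[[1]] * cfg$breathing_effect[[2]]
    p$a_lf <- base$a_lf * cfg$breathing_effect[[2]]
  }
  p
}

#' Generate one synthetic RR-interval recording
#'
#' Emits beats from a modulated point process: the instantaneous interval
#' is `RR0 * (1 + a_lf sin(2 pi 0.1 t + phi) + a_hf sin(2 pi f_resp t + psi))`
#' plus white jitter, evaluated at the current beat time. Condition effects
#' are applied per the configuration; paced breathing moves the respiratory
#' component to the pacing frequency and phase-locks it onto the 0.1 Hz
#' oscillation (metronome entrainment, common to both arms), while in the
#' cardiotoxicity arm the condition-induced changes of mean RR and of the
#' modulation amplitudes are scaled by the subject's `lambda` before use.
#' Ectopic beats are inserted with probability
#' `p_ectopic`: the affected interval shrinks to 0.7 of its value and the
#' following interval absorbs the difference (compensatory pause), so local
#' beat-time sums are preserved; both intervals are annotated `"ectopic"`.
#'
#' @param config a [sim_config()].
#' @param subject_params list with `rr0` (ms), `amp_mult` (shared amplitude
#'   multiplier), `phi`, `psi` (phases, radians), `lambda` (reactivity
#'   attenuation; 1 for controls) and `id`. See [generate_cohort()].
#' @param condition `"supine"`, `"standing"` or `"breathing"`.
#' @param timepoint `"baseline"` or `"followup"`.
#' @param seed optional integer; when given, the series is generated under
#'   its own `set.seed()` so identical arguments give byte-identical
#'   output. When `NULL`, the current RNG stream is consumed (used by
#'   [generate_cohort()] for its per-subject substreams).
#' @return An [rr_series()] spanning at least `duration_s` seconds.
#' @export
generate_rr_series <- function(config, subject_params = NULL,
                               condition = "supine", timepoint = "baseline",
                               seed = NULL) {
  validate_sim_config(config)
  condition <- match.arg(condition, .conditions)
  timepoint <- match.arg(timepoint, .timepoints)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sp <- subject_params %||% list(rr0 = config$base_rr_ms, amp_mult = 1,
                                 phi = 0, psi = 0, lambda = 1, id = "S001")
  base <- list(rr0 = sp$rr0, a_lf = config$a_lf * sp$amp_mult,
               a_hf = config$a_hf * sp$amp_mult, f_resp = config$f_resp_spont)
  tgt <- condition_params(config, base, condition)
  lam <- sp$lambda %||% 1
  eff <- Map(function(b, t) b + lam * (t - b), base, tgt)
  eff$f_resp <- tgt$f_resp  # breathing rate follows the protocol, not lambda
  psi <- if (condition == "breathing") sp$phi %||% 0 else sp$psi %||% 0
  if (eff$a_lf + eff$a_hf >= 1)
    stop("effective modulation amplitudes sum to >= 1; intervals could vanish")
  iv <- cpp_generate_beats(config$duration_s, eff$rr0, eff$a_lf, eff$a_hf,
                           0.1, eff$f_resp, sp$phi %||% 0, psi,
                           config$noise_sd_ms)
  lab <- rep("normal", length(iv))
  if (config$p_ectopic > 0 && length(iv) > 2) {
    u <- runif(length(iv))
    cand <- which(u < config$p_ectopic & seq_along(iv) < length(iv))
    # drop overlapping insertions so each pause absorbs exactly one ectopic
    keep <- cand[c(TRUE, diff(cand) > 1)]
    for (i in keep) {
      tot <- iv[i] + iv[i + 1]
      iv[i] <- 0.7 * iv[i]
      iv[i + 1] <- tot - iv[i]
      lab[c(i, i + 1)] <- "ectopic"
    }
  }
  rr_series(iv, labels = lab, condition = condition, timepoint = timepoint,
            subject_id = sp$id %||% "S001")
}

# Echo panel population parameters: per-variable baseline mean and SD for
# a pre-chemotherapy breast-cancer cohort (independent normals; no
# covariance structure is modelled).
echo_population <- function() {
  data.frame(
    field = c("lvef3d_pct", "lv_edv_ml", "lv_esv_ml", "gls_pct", "gcs_pct",
              "grs_pct", "las_pct", "lasr_pct", "lasp_pct", "lasc_pct",
              "ras_pct", "rasr_pct", "rasp_pct", "rasc_pct", "lv_md"),
    mean = c(63.53, 78.66, 28.74, -23.93, -30.78, 46.33, 60.23, 59.05,
             26.11, 34.5, 65.68, 64.85, 27.18, 37.63, 51.44),
    sd = c(6.71, 18.26, 11.97, 3.26, 3.99, 10.62, 22.3, 22.01, 10.76,
           17.23, 22.1, 21.96, 13.96, 14.29, 11.21))
}

draw_echo_panel <- function() {
  pop <- echo_population()
  v <- rnorm(nrow(pop), pop$mean, pop$sd)
  names(v) <- pop$field
  # physiological guards
  v["lvef3d_pct"] <- min(max(v["lvef3d_pct"], 54), 80)
  strains <- setdiff(pop$field, c("lvef3d_pct", "lv_edv_ml", "lv_esv_ml", "lv_md"))
  v[strains] <- sign(v[strains]) * pmin(abs(v[strains]), 95)
  as.list(v)
}

# Follow-up panel: measurement drift for everyone; cardiotoxicity subjects
# additionally receive (with probability p_echo_effect) a GLS-magnitude
# relative reduction > 10% and a modest LVEF decline.
draw_followup_panel <- function(baseline, cardiotox, cfg) {
  fu <- baseline
  for (f in names(baseline)) {
    rel <- rnorm(1, 0, 0.03)
    fu[[f]] <- baseline[[f]] * (1 + rel)
  }
  fu$lvef3d_pct <- baseline$lvef3d_pct + rnorm(1, 0, 1.5)
  fu$gls_pct <- baseline$gls_pct * (1 + rnorm(1, 0, 0.03))
  if (cardiotox && runif(1) < cfg$p_echo_effect) {
    fu$gls_pct <- baseline$gls_pct * (1 - runif(1, 0.12, 0.30))
    fu$lvef3d_pct <- baseline$lvef3d_pct - runif(1, 2, 8)
  }
  fu$lvef3d_pct <- min(max(fu$lvef3d_pct, 20), 80)
  fu
}

#' Generate a synthetic study cohort
#'
#' Draws group labels, per-subject physiological parameters, the six RR
#' recordings (three conditions at two timepoints), echocardiographic
#' panels and troponin flags for every subject. All randomness flows from
#' `config$seed` through per-subject substreams, so regenerating with the
#' same configuration reproduces the cohort exactly and subject k is
#' unchanged when `n_subjects` grows.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_cohort`; each element is a
#'   `synthetic_subject` list with `subject_id`, `group` (`"cardiotox"` or
#'   `"control"`), `recordings` (named `timepoint.condition` ->
#'   [rr_series()]), `echo` (named by timepoint), and `troponin_positive`
#'   (named logical per timepoint).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_subjects < 2) stop("need at least 2 subjects")
  subjects <- vector("list", config$n_subjects)
  for (k in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, k))
    id <- sprintf("S%03d", k)
    grp <- if (runif(1) < config$p_cardiotox) "cardiotox" else "control"
    sp <- list(
      rr0 = min(max(rnorm(1, config$base_rr_ms, config$subject_sd$rr0_sd_ms),
                    550), 1200),
      amp_mult = exp(rnorm(1, 0, config$subject_sd$log_amp_sd)),
      phi = runif(1, 0, 2 * pi), psi = runif(1, 0, 2 * pi),
      lambda = if (grp == "cardiotox") config$lambda_reactivity else 1,
      id = id)
    recordings <- list()
    for (tp in .timepoints)
      for (cond in .conditions)
        recordings[[paste(tp, cond, sep = ".")]] <-
          generate_rr_series(config, sp, cond, tp, seed = NULL)
    base_echo <- draw_echo_panel()
    echo <- list(baseline = base_echo,
                 followup = draw_followup_panel(base_echo,
                                                grp == "cardiotox", config))
    tro <- c(baseline = FALSE,
             followup = runif(1) < (if (grp == "cardiotox")
               config$p_troponin_case else config$p_troponin_control))
    subjects[[k]] <- structure(
      list(subject_id = id, group = grp, params = sp,
           recordings = recordings, echo = echo, troponin_positive = tro),
      class = "synthetic_subject")
  }
  structure(subjects, class = "synthetic_cohort", config = config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  grp <- vapply(x, `[[`, "", "group")
  cat(sprintf("<synthetic_cohort> %d subjects (%d cardiotox, %d control)\n",
              length(x), sum(grp == "cardiotox"), sum(grp == "control")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One tachogram text file per subject/timepoint/condition
#' (`S001_baseline_supine.rr`) plus `cohort.csv` holding group labels, the
#' echo panels (columns suffixed `_baseline` / `_followup`) and troponin
#' flags.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    for (key in names(s$recordings)) {
      rec <- s$recordings[[key]]
      write_tachogram(rec, file.path(dir, sprintf("%s_%s_%s.rr",
        s$subject_id, rec$timepoint, rec$condition)))
    }
    ev <- unlist(lapply(.timepoints, function(tp)
      setNames(unlist(s$echo[[tp]]),
               paste0(names(s$echo[[tp]]), "_", tp))))
    data.frame(subject_id = s$subject_id, group = s$group, t(ev),
               troponin_baseline = s$troponin_positive[["baseline"]],
               troponin_followup = s$troponin_positive[["followup"]])
  })
  write.csv(do.call(rbind, rows), file.path(dir, "cohort.csv"),
            row.names = FALSE)
  invisible(dir)
}
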