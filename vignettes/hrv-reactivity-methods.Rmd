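---
title: "Autonomic reactivity from RR tachograms: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autonomic reactivity from RR tachograms: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvreact)
```

## The measurement problem

Cardiac autonomic control is usually summarized from a resting recording,
but resting indexes are noisy one-point measurements. A *reactivity*
design instead perturbs the system — active standing (sympathetic
activation, vagal withdrawal) and paced breathing at 0.1 Hz (amplified
cardiorespiratory coupling at the baroreflex resonance) — and quantifies
the per-subject change of each HRV index relative to supine rest. The
package's working hypothesis, which the synthetic generator encodes as an
explicit parameter, is that subjects prone to chemotherapy-related cardiac
dysfunction show *attenuated* responses to both challenges.

This vignette documents the models and estimators, the conventions chosen
where the field admits more than one, and what the synthetic cohort does
and does not emulate.

## NN preprocessing

All indexes are computed from segments of exactly `L = 300`
normal-to-normal (sinus) intervals. A fixed *count* — rather than a fixed
duration — is used deliberately: several estimators (notably SDNN and the
Poincaré SDs) have small-sample behaviour that depends on the number of
intervals, so holding the count constant removes a nuisance difference
between fast and slow hearts. At typical rates a 300-interval segment
covers roughly five minutes, the conventional short-term HRV window.

Cleaning (`clean_to_nn()`) is a single forward pass. An interval is
excluded when it

* already carries an `ectopic`/`artifact` annotation,
* deviates by more than 20% from the median of the previous 11 intervals
  that survived as normal, or
* lies outside 300–2000 ms.

All three thresholds are configurable (`nn_filter_config()`). The
running-median rule is an automated stand-in for the visual artifact
screening a human scorer would perform; 20%/11 beats is standard tachogram
practice — wide enough that respiratory oscillations at physiological
amplitude pass, narrow enough that a 30% early ectopic and its
compensatory pause are both caught. Flagged intervals are *excluded, never
interpolated*: the analysis series must contain sinus beats only, and
interpolation would manufacture beats. Because the surviving-normal
history of any interval is unchanged by a second pass, the filter is
idempotent (this is tested).

Segment selection (`select_segment()`) discards the first 180 s
(postural/device stabilization), then scans every contiguous window of
`L` NN intervals and keeps the one with minimal SDNN, earliest on ties.
"Stable segment" has no unique definition in the literature; the
minimum-SDNN convention is the package's, chosen because it is
deterministic, testable against an exhaustive scan, and selects exactly
what a human scorer looks for (a stationary stretch). A recording that
cannot supply `L` normal intervals after the skip is an explicit
insufficient-data error naming subject, timepoint and condition — never a
silently shorter segment.

## Index estimators

**Time domain.** Mean NN; mean HR defined as `60000 / mean NN` (not the
mean of instantaneous rates — the two differ by Jensen's inequality, and
the reciprocal-of-mean convention is the common one); SDNN as the sample
standard deviation (denominator N − 1 everywhere in this package); pNN50
with *strict* inequality (|ΔNN| > 50 ms).

**Frequency domain.** The tachogram — NN value against the beat time
ending it — is linearly interpolated and resampled at 3 Hz, which places
the Nyquist frequency (1.5 Hz) far above the HF band edge (0.4 Hz). The
PSD is estimated by Welch's method: 256-sample (~85 s) windows, Hann
taper, 50% overlap, per-window mean removal, one-sided normalization such
that the integral of the PSD over frequency equals the variance of the
detrended samples. The window length trades frequency resolution
(3/256 ≈ 0.012 Hz, comfortably resolving the 0.04 Hz LF lower edge)
against the number of averaged windows (~6 for a 300-interval segment).
All settings are recorded in the output and configurable
(`hrv_settings()`); no smoothness-priors or polynomial detrending is
applied. Band powers are trapezoidal integrals with the PSD interpolated
at the exact band edges; the 0.15 Hz boundary belongs to HF by
convention. Normalized units divide by LF + HF by default (a total-power
denominator is available via `nu_denominator = "total"`), so
`lf_nu + hf_nu = 100` whenever defined. Undefined ratios (zero HF, zero
total power) are flagged `NA`, never ±Inf.

**Poincaré.** SD1/SD2 are computed by rotating the lag-1 return map by
45°: `u = (NN[i+1] − NN[i])/√2`, `v = (NN[i+1] + NN[i])/√2`; SD1 = sd(u),
SD2 = sd(v). For axes fixed on the identity line this *is* the ellipse
axis computation — no least-squares ellipse regression is involved. Both
SD2/SD1 and SD1/SD2 are reported because both conventions circulate.

## Reactivity deltas and ROC

`compute_deltas()` defaults to **Δ = maneuver − supine**. The opposite
convention exists in parts of the literature; a configuration switch
(`sign_convention = "supine_minus_maneuver"`) flips it. The default was
chosen so that an index that rises under challenge yields a positive
delta, making "blunted reactivity" read as "smaller Δ", and cut-offs for
predicting dysfunction naturally take the form "Δ ≤ c".

`roc_curve()` sweeps every distinct score as a threshold; tied scores
collapse into one step, so the trapezoidal AUC equals the tie-corrected
Mann–Whitney statistic exactly (tested by exhaustive pair counting, and
cross-checked against pROC). By default the orientation (case-positive
when the score is ≤ or ≥ the threshold) is auto-selected to give
AUC ≥ 0.5 and is reported. One consequence matters for calibration
studies: under the null, auto-orientation makes the AUC ≥ 0.5 by
construction, so null-calibration and power analyses in this package's
tests and acceptance script fix the orientation to the prespecified
`positive_if_le` (cases have *lower* reactivity) instead.

`best_cutoff()` minimizes the Euclidean distance
√((1 − sens)² + (1 − spec)²) from each empirical curve point to the ideal
classifier (0, 1) — distance to the point, not perpendicular distance to
a line — earliest threshold on exact ties. No interpolation between curve
points is performed before the minimization. AUC inference uses the
Hanley–McNeil standard error with a two-sided normal test against 0.5;
it is simpler than DeLong, adequate at these sample sizes, and clearly
swappable behind `auc_inference()`. A perfect AUC gives SE = 0 and is
flagged as a boundary case rather than hidden.

## Cohort statistics

* `normality_gate()`: one-sample Kolmogorov–Smirnov against a normal with
  estimated mean/SD; p < 0.05 triggers a log10 transform. Using estimated
  parameters without the Lilliefors correction makes the gate
  conservative (it transforms too rarely rather than too often); this
  mirrors the common clinical toolchain and is documented rather than
  corrected. Non-positive values under a triggered transform are an
  error — the offset/exclusion decision belongs to the caller.
* `compare_groups()`: pooled-variance Student's t (unpaired) or
  difference-score t (paired). Zero-variance degenerate input yields
  flagged `NA` statistics, not an error.
* `rm_anova()`: subject-blocked one-way ANOVA via `aov`, F on
  (k − 1, (k − 1)(n − 1)) df, no sphericity correction (a documented
  limitation; with three conditions the effect is modest). All-constant
  input is handled by comparing the sums of squares against a relative
  threshold before forming F.
* `categorical_test()`: chi-squared without continuity correction when
  all expected counts ≥ 5, Fisher's exact (two-sided,
  point-probability summation) otherwise; the choice is a pure function
  of the expected counts and is reported.
* `pearson_matrix()`: unadjusted pairwise p-values — no multiplicity
  correction is applied anywhere, but the number of tests performed is
  returned so a reader can apply one.
* `las_significant_reduction()`: follow-up LASr below the 35% normal
  threshold (when baseline ≥ 35%) or a > 10% relative reduction; from a
  sub-threshold baseline only the relative rule applies.
* `classify_cardiotoxicity()`: echo criterion = follow-up LVEF < 53% with
  an absolute drop ≥ 10 points, *or* a > 10% relative reduction of GLS
  magnitude (|GLS| shrinking toward zero is function loss); troponin
  criterion = conversion from negative baseline to positive follow-up.
  Published guideline thresholds vary by society and year, so every
  threshold is a named, configurable default (`ctox_criteria()`) — these
  are explicit stand-ins, not claims about any particular study's
  settings.

## The synthetic cohort

`generate_rr_series()` emits beats from a modulated point process:

    m(t) = RR0 · [1 + a_lf sin(2π·0.1·t + φ) + a_hf sin(2π·f_resp·t + ψ)] + ε

evaluated at the current beat time, with the next beat one interval
later. This interval-by-interval evaluation is simpler than integrating
an IPFM model and reproduces the band-power structure the analysis needs;
it is documented as a modelling choice, not physiology. Defaults:
RR0 = 850 ms (population SD 60 ms between subjects), a_lf = 0.03,
a_hf = 0.025 with a shared log-normal subject multiplier (SD 0.15 on the
log scale), spontaneous breathing at 0.25 Hz, jitter SD 5 ms. These place
supine SDNN near 20–60 ms — a physiological resting range — and keep the
oscillation extremes inside the 20% NN-filter band, so cleaning removes
injected ectopics rather than genuine modulation.

Condition effects: standing shortens RR0 by 12%, scales a_lf by 1.6 and
a_hf by 0.5 (sympathetic shift); paced breathing moves the respiratory
component to 0.1 Hz, scales it by 2.0 and total variability by 1.2
(resonant coupling). Under paced breathing the respiratory component is
also *phase-locked* onto the 0.1 Hz component. This is deliberate: with
two oscillations at the identical frequency and independent random
phases, their interference makes the breathing-condition variance depend
on the phase difference — a subject-level lottery unrelated to
reactivity. Physically, a metronome entrains both the mechanical and the
baroreflex oscillation; the frequency and the lock are therefore part of
the stimulus and common to both arms, while the *amplitude* gains are the
autonomically mediated response.

The cardiotoxicity arm multiplies every condition-induced change of RR0
and the amplitudes by `lambda_reactivity` ∈ [0, 1]; λ = 1 reproduces the
control law exactly (the null), λ = 0 abolishes reactivity. Ectopic beats
(default probability 0.003/beat) replace an interval by 0.7 of its value
and add the remainder to the next interval, preserving local beat-time
sums; the 0.7 factor is invented, chosen so that *not* cleaning visibly
inflates SD1 — which makes the cleaning stage's effect testable.

Echo panels are drawn as independent normals at published population
scale (e.g. baseline 3D LVEF 63.5 ± 6.7%); cardiotoxic subjects receive,
with probability 0.9, a follow-up GLS-magnitude reduction of 12–30% plus
a modest LVEF decline, and a positive follow-up troponin with
probability 0.7 (2% false-positive rate in controls). No covariance
between echo variables is modelled.

Randomness: one master seed; subject k re-seeds from a deterministic
substream value, so subject k's data are invariant to the cohort size and
all outputs are bit-reproducible.

**What the generator does not emulate:** nonstationarity and trends
within a recording, 1/f background spectra, respiratory frequency drift,
atrial fibrillation or other non-sinus rhythms beyond the simple ectopic
morphology, missing data mechanisms correlated with disease, and any
covariance between echocardiographic variables. Passing the end-to-end
tests therefore demonstrates that the *pipeline* recovers the planted
structure under clean generative assumptions — it is not evidence about
real patients.

## Problem sizes and numerical conventions

The test suite exercises: oracle equivalence of the time-domain and
Poincaré estimators on 1,000 random 300-interval segments at 1e−12
relative tolerance; Welch normalization on 100 white-noise replicates
(5%) and an analytic 0.1 Hz sinusoid (10% on LF power); exact AUC
equality with pair counting on 200 random score sets of size ≤ 20;
type-I error of the t-test (4,000 null replicates), repeated-measures
ANOVA (1,000), AUC test (2,000) and Pearson test (2,000) within
(0.03, 0.08) at α = 0.05; and end-to-end recovery over 200 simulated
cohorts of 50 subjects at λ = 0.3 plus 200 null cohorts at λ = 1. These
sizes keep the full suite under a few minutes on one CPU while leaving
Monte-Carlo margins well clear of the asserted bounds.

Ties are always broken toward the earliest candidate (segment windows,
ROC cut-offs). Degenerate inputs produce flagged `NA`s where a downstream
analysis can proceed without the value (ratios, correlations with a
constant column, zero-variance t-tests) and errors where it cannot
(empty series, missing supine condition, missing follow-up echo,
zero-margin tables).

## Known limitations

* The Welch settings, the normalized-units denominator, the 0.15 Hz
  boundary assignment, and the Δ sign are conventions; all are
  configurable and recorded in outputs, but results are only comparable
  across studies that share them.
* Hanley–McNeil inference is asymptotic and mildly miscalibrated for
  extreme AUCs at small n; the boundary flag marks the worst case.
* The repeated-measures ANOVA assumes sphericity.
* The KS normality gate with estimated parameters under-transforms.
* The synthetic cohort's effect sizes are planted, not estimated from
  data; recovery rates quantify pipeline correctness, not clinical
  discriminative performance.
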