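# hrvreact

Heart-rate-variability (HRV) reactivity analysis for early cardiotoxicity
screening in patients starting cardiotoxic chemotherapy.

Anthracycline-based regimens can injure the myocardium well before the left
ventricular ejection fraction falls. Because cardiac autonomic control reacts
to physiological challenges within seconds, a *blunted* HRV response to a
maneuver — standing up, or breathing at a paced 0.1 Hz — is a candidate
early marker. `hrvreact` implements the full analysis chain for a protocol
with three recording conditions (supine rest, active standing, paced
breathing) at two timepoints (baseline and follow-up):

1. **NN preprocessing** — annotate/exclude ectopic and artifact intervals
   with a running-median filter (20% deviation from the median of the
   previous 11 accepted intervals, plus a 300–2000 ms physiological window),
   then select the most stable contiguous window of exactly 300
   normal-to-normal (NN) intervals after the first 180 s (minimum-SDNN
   criterion).
2. **HRV indexes per segment** — time domain (mean NN, mean HR = 60000 /
   mean NN, SDNN, pNN50 with strict > 50 ms differences); frequency domain
   (tachogram resampled at 3 Hz by linear interpolation, Welch periodogram
   with 256-sample Hann windows at 50% overlap, band powers LF 0.04–0.15 Hz
   and HF 0.15–0.4 Hz, normalized units `lf_nu = 100·LF/(LF+HF)`,
   `log10(LF/HF)`); Poincaré descriptors (SD1/SD2 via the exact 45°
   rotation onto the identity-line axes).
3. **Reactivity deltas** — Δ(index, maneuver) = value(maneuver) −
   value(supine) per subject.
4. **ROC analysis** — empirical ROC per delta with tie-grouped thresholds,
   trapezoidal AUC, Hanley–McNeil CI and test against AUC = 0.5, and the
   best cut-off by shortest Euclidean distance to the ideal point (0, 1).
5. **Cohort statistics** — Kolmogorov–Smirnov-gated log10 transform,
   pooled/paired t-tests, subject-blocked repeated-measures ANOVA,
   chi-squared/Fisher selection by expected counts, Pearson correlation
   panels, the left-atrial reservoir strain (LASr) significant-reduction
   rule (< 35% threshold or > 10% relative drop), and cardiotoxicity
   classification from echo (LVEF/GLS) and troponin criteria.

Because clinical recordings of this kind are rarely shareable, the package
ships a first-class **synthetic cohort generator**: a modulated point
process with a 0.1 Hz (baroreflex) and a respiratory component, condition
effects for standing and paced breathing, a reactivity-attenuation
parameter `lambda_reactivity` for the cardiotoxicity arm, ectopic-beat
insertion, and echocardiographic panels drawn at published population
scale. Every downstream stage is tested end-to-end against it.

## Worked example

```r
library(hrvreact)

cfg <- sim_config(n_subjects = 12, p_cardiotox = 0.5, seed = 7,
                  lambda_reactivity = 0.3)
cohort <- generate_cohort(cfg)

rec <- cohort[[1]]$recordings[["baseline.supine"]]
seg <- select_segment(clean_to_nn(rec), L = 300, skip_s = 180)
seg
#> <nn_segment> S001 / baseline / supine: 300 NN intervals from t = 181.1 s

round(unlist(compute_hrv(seg)), 2)
#>    mean_nn_ms   mean_hr_bpm       sdnn_ms     pnn50_pct  lf_power_ms2
#>        887.84         67.58         21.88          0.00        263.13
#>  hf_power_ms2         lf_nu         hf_nu   log10_lf_hf        sd1_ms
#>        138.16         65.57         34.43          0.28         14.62
#>        sd2_ms sd2_sd1_ratio sd1_sd2_ratio
#>         27.31          1.87          0.54
```

The supine segment of the first subject has a mean heart rate of 67.6 bpm,
SDNN of 21.9 ms and a mild LF dominance (`lf_nu` 65.6) — a typical resting
profile. Reactivity deltas and their ROC performance as predictors of the
generator's cardiotoxicity arm:

```r
deltas <- cohort_delta_table(cohort)
rt <- roc_table(deltas)
subset(rt, index %in% c("sdnn_ms", "sd1_ms") & maneuver == "breathing")
#>      index  maneuver n_case n_control auc ci_low ci_high p_value cutoff
#> 16 sdnn_ms breathing      7         5   1      1       1       0  26.68
#> 23  sd1_ms breathing      7         5   1      1       1       0   1.18
#>    cutoff_label sensitivity_pct specificity_pct
#> 16     <= 26.68             100             100
#> 23     <= 1.183             100             100
```

With the attenuation at `lambda_reactivity = 0.3` the paced-breathing SDNN
and SD1 deltas separate the two arms completely in this small cohort: a
subject whose SDNN rises by less than 26.7 ms under paced breathing is
flagged. The `<=` direction encodes that *smaller* reactivity predicts
cardiotoxicity.

The whole chain — simulation, preprocessing, indexes, deltas, ROC, group
statistics, classification, manifest — runs as one call:

```r
manifest <- run_pipeline(list(sim = list(n_subjects = 50,
                                         p_cardiotox = 0.46,
                                         lambda_reactivity = 0.3)),
                         out_dir = "run1", seed = 11)
```

A thin command-line wrapper with `simulate`, `validate`, `run` and
`show-defaults` subcommands is installed at
`inst/scripts/hrvreact-cli.R`.

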