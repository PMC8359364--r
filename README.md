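# respgate

Retrospective respiratory-gating analysis for whole-heart 4D flow MRI, for
imaging scientists comparing gating signals (in-bore camera vs liver-lung
navigator) and quantifying what gating buys in image quality.

Free-breathing 4D flow acquisitions are blurred by respiratory motion unless
each readout is labelled with the breathing state at its acquisition time
and only end-expiratory data are reconstructed. A camera reports chest
motion at 20 Hz in arbitrary units; a navigator reports liver position at
2 Hz in millimetres. The two are only comparable after reduction to a common
*respiratory phase*, and `respgate` implements that reduction and everything
the comparison study around it needs:

* **Phase binning** (`bin_phases()` and the individual steps): rescale to
  zero median, smooth 1 s, two-pass extrema detection (minimal peak distance
  from a 45 bpm ceiling, prominence threshold = 1/4 of the median
  trough-to-peak swing), alternation correction, and mapping of each sample
  to bins 1–100 — bins 1–40 over inspiration (trough→peak), 41–100 over
  expiration (peak→trough). Accepting bins 41–100 is the 60% expiration
  acceptance.
* **Agreement between modalities** (`phase_cross_correlation()`): peak
  normalised cross-correlation `C_phase` of the two bin series and the lag
  at the peak, the phase delay `d_phase` (ms), plus
  `mismatch_percent(delay, rate)` = `100·|delay| / (60000/rate)` to express
  a delay as a fraction of the breathing cycle, and boxplot-style amplitude
  summaries with `W = Q1/Q3 ∓ 1.5·IQR` whiskers.
* **Image quality** (`compute_quality()`): ROI SNR (time-averaged liver
  slice mean / time-averaged lung slice SD) and the liver–lung edge width
  LLE — the mean logistic scale `w` of sigmoid fits
  `b + a/(1 + exp(−(z − z0)/w))` to the 100 through-edge line profiles of a
  10×10×30 ROI (voxels; larger = blurrier).
* **Statistics** (`rm_anova_wilks()`, `bonferroni_pairwise()`,
  `krippendorff_alpha_ordinal()`, `bland_altman()`,
  `one_sided_mean_test()`): multivariate repeated-measures ANOVA via
  Hotelling's T² (`Λ = 1/(1 + T²/(n−1))`, `F` on `(k−1, n−k+1)` df, partial
  η² = 1 − Λ), Bonferroni-corrected paired comparisons with adjusted CIs,
  ordinal Krippendorff's α, and Bland–Altman bias ± 1.96·SD limits.
* **Synthetic data** (`gen_breathing_waveform()`, `gen_modality_pair()`,
  `gen_phantom_volume()`, `gen_ordinal_ratings()`,
  `gen_condition_table()`): every input above, with known ground truth, so
  the full pipeline runs without patient data.

All user-facing functions take a data frame first and return tibbles;
fitted objects support `tidy()` / `glance()` and result types have
`autoplot()` methods.

## Worked example

```r
library(respgate)

latent <- gen_breathing_waveform(breathing_params(
  rate_bpm = 15, insp_fraction = 0.4, duration_s = 90, seed = 1
))
pair <- gen_modality_pair(latent, nav_scale_mm = 12,
  cam_params = modality_params(noise_sd = 0.03, drift_amp = 0.2,
                               outlier_rate_hz = 0.05),
  nav_params = modality_params(noise_sd = 0.03, drift_amp = 0.2), seed = 2)

cam_phase <- bin_phases(pair$camera)   # 20 Hz camera trace -> phase bins
nav_phase <- bin_phases(pair$navigator)
round(100 * mean(cam_phase$accepted[cam_phase$bin > 0]), 1)
#> [1] 61.4
phase_cross_correlation(cam_phase, nav_phase)
#> # A tibble: 1 × 4
#>   C_phase d_phase_ms lag_window_ms n_overlap
#>     <dbl>      <dbl>         <dbl>     <int>
#> 1   0.935          0          2000      1749
mismatch_percent(63, 40)
#> [1] 4.2
```

61.4% of assigned samples fall in the accepted expiration bins (the 60%
expiration acceptance under this trace's 40:60 inspiration:expiration
split); the camera- and navigator-derived phases correlate at 0.935 with no
measurable delay, and a hypothetical 63 ms delay would mismatch only 4.2%
of a breathing cycle even at 40 breaths/minute.

A whole synthetic cohort, with per-condition image quality and the study
statistics:

```r
rep <- run_cohort_study(study_config(n_subjects = 8, seed = 1))
rep
#> <study_report> 8 subjects, seed 1
#>   mean C_phase = 0.919, mean |d_phase| = 31 ms
#>   cam  SNR =  12.63  LLE =  2.00 voxel
#>   nav  SNR =  12.58  LLE =  2.00 voxel
#>   no   SNR =  12.52  LLE =  2.38 voxel
tidy(rep$stats$lle_anova)
#> # A tibble: 1 × 7
#>   term      wilks_lambda statistic   df1   df2    p.value partial_eta_sq
#> 1 condition       0.0172      171.     2     6 0.00000513          0.983
```

The ungated ("no") condition shows the motion-blur penalty — a ~0.4 voxel
wider liver–lung edge than either gated reconstruction — and the ANOVA
rejects equality of conditions; `write_report(rep, "out/")` serialises
agreement, quality and statistics tables plus a markdown summary.

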