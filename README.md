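# emohyst

Analysis of **perceptual hysteresis in dynamic facial emotion
recognition**, at the behavioural and ROI-BOLD level, for experiments in
which a face morphs from a *source* emotion (E1) through a *neutral*
expression (N) into a *target* emotion (E2) and the perceived switch point
depends on the direction of change.

The package is aimed at cognitive-neuroimaging researchers who want a
tested, reproducible implementation of this analysis chain — and a
synthetic observer/BOLD generator with known ground truth, so that every
stage can be validated end to end without human data.

## The model in brief

**Stimulus.** One dynamic transition is an array of 81 morph frames in
2.5 % steps (40 intermediates on each side of the shared neutral frame).
Middle frames are shown for 113.92 ms (= 9000/79 ms, a 9-s morph), the two
endpoint expressions for 500 ms each, so one trial lasts 10 s. Every frame
maps to a *signed position* s = E2% − E1% ∈ [−100, +100], with neutral
at 0.

**Hysteresis metric.** On dynamic trials observers press at the onset (P1)
and offset (P2) of the interval they perceive as neutral; trials with
fewer than two presses are excluded. Per participant × emotion pair ×
direction, the mean P2 border is the *dynamic inflection* — the switch to
the alternative percept. The no-history *static inflection* comes from
3-way classifications (negative / neutral / positive) of nine static probe
frames: the signed positions of the earliest and latest frames whose modal
report is neutral. The metric is

    h = |dynamic inflection| − |static inflection|

with labels **positive** (h > tol: the percept persists, the switch
happens later than without history), **negative** (h < −tol), or **none**
(|h| ≤ tol, default tol = 1.25 %, half a morph step).

**Imaging.** ROI time series are analysed with an OLS GLM (HRF-convolved
condition boxcars, 3-cycle GLM-Fourier high-pass, detrended motion
confounds; optional AR(1) prewhitening), BOLD percent signal change
100·(x − x̄)/x̄ with hemodynamically delayed event-related averages and
within-subject (Morey-corrected) SEMs, generalized PPI (interaction
regressors z(seed)·X_c formed at the hemodynamic level, no deconvolution),
and sliding-window (10 s = 5 TRs) partial Spearman correlations with
Fisher z, conditioned on a noise ROI. Group inference uses one-sample t
and Wilcoxon signed-rank tests (exact for n ≤ 25 untied), with
Benjamini–Hochberg FDR across ROIs.

## Worked example

Simulate one observer through three dynamic and three static runs with a
known hysteresis displacement (here: +10 % for anger–happiness in both
directions, +15 % in direction 2 only for the sadness pairs), then recover
the metric:

```r
library(emohyst)

sched <- lapply(1:3, function(r) build_dynamic_run_schedule(seed = r))
stat  <- lapply(seq_along(emotion_pairs()), function(i)
  build_static_run_schedule(emotion_pairs()[i], seed = 10 + i))

obs <- observer_params(
  h_shift = matrix(c(10, 10, 0, 15, 0, 15), 3, 2, byrow = TRUE),
  motor_sd = 0.1, miss_prob = 0.05)

ints <- do.call(rbind, lapply(1:3, function(r) {
  resp <- simulate_dynamic_reports(sched[[r]], obs, seed = 100 + r)
  extract_neutral_intervals(resp, sched[[r]])$intervals
}))
tp <- dynamic_transition_points(ints)

sb <- do.call(rbind, lapply(1:3, function(i) {
  cls <- simulate_static_classifications(stat[[i]], obs, seed = 200 + i)
  si  <- static_inflection(cls)
  data.frame(pair = emotion_pairs()[i], lo_pos = si$lo_pos, hi_pos = si$hi_pos)
}))

print(hysteresis_results(tp, sb), digits = 3)
```

```
               pair direction dynamic_inflection static_inflection  value    label
1   anger-happiness         1               29.7                20  9.722 positive
2   anger-happiness         2              -30.4               -20 10.417 positive
3     sadness-anger         1               20.7                20  0.682     none
4     sadness-anger         2              -35.8               -20 15.750 positive
5 sadness-happiness         1               21.0                20  1.000     none
6 sadness-happiness         2              -35.9               -20 15.909 positive
```

The recovered values sit within a fraction of a morph step of the injected
shifts, and the labels show the designed asymmetry: positive hysteresis in
direction 2 of the sadness pairs, none in direction 1. Direction-2
inflections are negative because that trajectory runs from +100 to −100 on
the signed axis; the metric uses absolute switch positions.

The full chain — including BOLD simulation, ROI GLM contrasts between
directions with and without dominant positive hysteresis, gPPI of the
right anterior insula seed against mPFC, and sliding-window correlation
dynamics — runs as one deterministic pipeline:

```r
report <- run_pipeline(default_config(), out_dir = "out")
report$ppi$group        # insula-mPFC coupling contrast across subjects
report$sliding$comparison  # per-timepoint paired Wilcoxon on Fisher z
```

Identical configurations produce byte-identical outputs; every output file
carries a JSON sidecar with the configuration hash, seed and package
version.

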