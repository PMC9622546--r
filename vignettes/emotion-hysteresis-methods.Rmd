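---
title: "Methods: perceptual hysteresis in dynamic facial emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perceptual hysteresis in dynamic facial emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
stimulus and task model, the hysteresis metric, the imaging analyses, the
synthetic-data generator that stands in for human data, and the numerical
and design choices made where the problem left them open.

## The stimulus model

A dynamic transition morphs a face from a *source* emotion (E1) through a
*neutral* expression into a *target* emotion (E2) in steps of 2.5 % per
frame: 40 intermediates on each side of the shared neutral frame, 81
frames in all (`morph_params()`). Each middle frame is displayed for
113.92 ms and the two endpoint expressions for 500 ms, so the morph
portion lasts 79 × 113.92 ms = 8,999.68 ms (9 s) and the whole trial
9,999.68 ms (10 s). The stated frame duration and the stated frame rate of
such protocols are not mutually exact; we take 113.92 ms ≈ 9000/79 ms as
definitive because it makes both the 9-s morph and the 10-s trial come out
right.

Every frame has a single coordinate on a **signed stimulus axis**,
s = E2% − E1% ∈ [−100, +100] (`signed_position()`), neutral at 0. A single
axis makes "the absolute value of the perceptual switch" well defined in
both stimulation directions: direction 1 plays the sequence forward
(s: −100 → +100), direction 2 in reverse. Frames are 1-based; times are
milliseconds from trial onset. `time_to_frame()` is the left-continuous
step function inverting the display schedule; it is exercised in the tests
against a brute-force scan of cumulative frame onsets over a 1-ms grid.

**Run layout.** A dynamic run holds 24 transition trials (4 × 3 emotion
pairs × 2 directions) in three sequences of eight, each transition
followed by a neutral-to-neutral control transition, pseudo-randomised so
consecutive transitions never share an actor. The exact placement of
fixation blocks within a run is not fully determined by the protocol
description; we place one 10-s fixation at run start (opening the first
sequence), before sequences two and three, and at run end (520 s of
stimulation inside a 280-volume, TR = 2 s scan). A static run presents 12
repetitions of 9 probe frames of one pair (108 image trials of 2 s, each
followed by a 2-s neutral snapshot) in three blocks with fixation before
each block and at run end (472 s inside a 249-volume scan). The static-run
arithmetic cannot be made to fill the scan exactly under any fixation
count consistent with the description; scans are therefore allowed to
outlast stimulation, and a schedule only warns when it would *exceed* the
scan.

## The hysteresis metric

On dynamic trials, observers press at the perceived onset (P1) and offset
(P2) of the neutral interval. Trials with fewer than two presses cannot
define an interval and are excluded and counted
(`extract_neutral_intervals()`). Press times map through `time_to_frame()`
(mirrored for direction 2) to signed positions; per participant × pair ×
direction the two borders are averaged (`dynamic_transition_points()`).

**Which border is "the switch"?** The metric compares the switch *to the
alternative percept*, which we take to be the P2 border — where perception
commits to the target emotion. The P1 border is computed and exported but
does not enter the metric. This is the one defensible reading of a single
switch point per direction; both borders remain available for other
analyses.

The no-history reference comes from the static task: three-way
classifications (E−/N/E+) of the nine probe frames. A frame counts as
"reported neutral" when N is its **modal** choice across the 12
repetitions (ties resolved in favour of N); the signed positions of the
earliest and latest such frames are the static borders
(`static_inflection()`). The per-frame percentage of neutral reports is
exported alongside so other thresholds can be applied. The no-history
switch for direction 1 (towards E2) is the upper border, for direction 2
the lower one — the border on the target side.

The metric is `value = |dynamic| − |static|` with labels positive /
negative / none under an equality tolerance `tol` (`hysteresis_metric()`).
Exact float equality would be meaningless; the default `tol = 1.25` % is
half a morph step, the resolution of the stimulus axis. Missing groups
(e.g. no neutral-modal frame) propagate as `NA` markers and are dropped
pairwise in group tests.

**Group statistics.** Direction comparisons use the paired two-tailed
Wilcoxon signed-rank test (`wilcoxon_signed_rank()`): zero differences
dropped, exact enumeration (`psignrank`) for n ≤ 25 without ties,
otherwise a tie-corrected, continuity-corrected normal approximation. We
implement the statistic directly because the standardised Z is the
quantity conventionally reported for these comparisons;
`stats::wilcox.test` serves as the independent oracle in the tests, and a
sign-flip permutation oracle checks the approximate branch. Error bars use
the within-subject SEM: rows recentred to the grand mean, per-condition
SD/√n, Morey factor √(C/(C−1)) (`within_subject_sem()`).

## The synthetic observer

`observer_params()` carries a three-way ordinal psychometric model of the
static task — logistic boundaries at `static_center_lo/hi` (default
±30 %) with steepness `static_slope` (default 1 per percent) — and a
ground-truth hysteresis displacement `h_shift` (percent per pair ×
direction) that delays both neutral borders along the trajectory on
dynamic trials.

The one genuinely open design question is what the observer's dynamic
borders should be at `h_shift = 0`. We define them as the **implied static
band**: the extreme probe frames its own classifier labels neutral in the
noise-free limit (`implied_neutral_band()`, ±20 % under the defaults).
This makes the closed loop exact — a noiseless unbiased observer's P1/P2
map back to the measured static borders precisely, and the recovered
metric is unbiased for the injected shift. Tying the dynamic borders to
the psychometric boundaries themselves (±30) instead would build a
granularity bias into every simulation, because the static estimator can
only resolve the 9-frame probe grid; the hysteresis metric would then be
biased by the grid offset even for a perfect observer, which is a property
of the estimator, not of hysteresis.

Presses are generated at the midpoint of the border frame's display
interval before motor noise is added. Pressing at frame *onset* would
interact with the floor-type `time_to_frame()` mapping to bias recovered
positions by about half a frame (−1.25 %); the midpoint convention cancels
this.

Remaining observer parameters, chosen once as realistic for this kind of
task: `motor_sd = 0.1` s press jitter; `miss_prob = 0.05` per press
(≈ 10 % of trials excluded — same order as typical two-press tasks);
`false_alarm_prob = 0.05` for spurious press pairs on neutral-to-neutral
control trials (such tasks report ≈ 5 % two-response control trials). The
pipeline's default shift map injects positive hysteresis in direction 2
only for the sadness pairs (+15 %) and symmetrically (+10 %) for
anger–happiness, with a between-subject SD of 5 % — the asymmetric
dominance structure this class of experiment exhibits. These defaults are
the study conditions of the synthetic experiment; they are not tuned
per-analysis.

## The BOLD generator and GLM machinery

`simulate_bold_dataset()` generates, per run: a seed ROI (right anterior
insula) as HRF-convolved condition boxcars times `beta_task` plus AR(1)
noise; target ROIs as task signal **plus condition-modulated seed
coupling** `beta_ppi[c] · z(seed) · X_c` — the exact generative
counterpart of the no-deconvolution gPPI model — plus slow cosine drift
and AR(1) noise; a white-matter ROI carrying pure noise; and six
random-walk motion parameters (a nuisance table only; motion does not
enter the signal). Defaults: `noise_sd = 1` (stationary SD, percent-signal
units against task amplitudes ≈ 1), `ar1_rho = 0.3` (typical for TR 2 s),
`drift_amp = 1` at 1–2 cycles/run with random phase — deliberately inside
the span of the 3-cycle Fourier set so the high-pass can absorb it
exactly — and `motion_sd = 0.02`. The default coupling map gives mPFC a
stronger seed coupling in direction 1 (0.6) than direction 2 (0.2):
insula–mPFC connectivity is *lower* when positive hysteresis dominates,
which is the effect the connectivity analysis is built to detect. Face
regions (rFFA/rSTS) respond more, and the insula less, in direction 2.

One consequence worth knowing: condition-modulated coupling is unmodelled
signal for a task-only GLM, so the *target* ROI's task contrast absorbs
part of it. Apparent activation differences in a coupling target are
expected under this generator unless interaction terms are included — the
gPPI model includes them.

**HRF.** The protocol names no HRF; we use the canonical double-gamma
(response Γ(6,1) peaking at 5 s, undershoot Γ(16,1) at 15 s, ratio 6),
truncated at 32 s and normalised so the *continuous* kernel peaks at 1
(peak located on a 1-ms grid, making samplings at different TRs mutually
consistent).

**Design and fit.** `build_design()` assembles HRF-convolved condition
boxcars, sine/cosine pairs at 1–3 cycles per run (the "GLM-Fourier"
high-pass as regressors rather than a pre-filter, which keeps the
degrees-of-freedom bookkeeping inside the model), linearly detrended
motion confounds ("detrended" is otherwise unspecified; removing a linear
trend per column is the minimal reading), and an intercept. Empty columns
and rank deficiencies are flagged, not dropped; singular fits fall back to
the Moore–Penrose pseudo-inverse with a warning. `fit_glm()` is OLS;
`prewhiten = TRUE` adds iterated Cochrane–Orcutt AR(1) whitening
(small-sample bias-corrected lag-1 estimate, restarting at run
boundaries). Naive OLS t values under AR(1) noise at ρ = 0.3 are
anti-conservative (empirically ≈ 7 % false positives at |t| ≥ 2);
prewhitened subject-level (three-run) fits are calibrated (≈ 2–5 %), so
inference-bearing fits — gPPI contrasts and the pipeline's task
contrasts — prewhiten by default.

Multi-run (fixed-effects) fits concatenate runs with shared condition
columns and per-run intercept/Fourier/motion blocks
(`concat_run_designs()`). Percent signal change is computed against the
series mean; event-related averages sample a hemodynamically delayed
peristimulus window — trial onset + 6 s to onset + 20 s at TR resolution
(`delay_s = 6`, `window_s = 14`) — averaged within, then across
participants, with within-subject SEMs and per-timepoint paired Wilcoxon
flags. The stimulus occupies peristimulus times 6–16 s on this axis.
Trial-level grouping for the direction contrasts is **per direction**, not
per trial: each pair × direction cell is labelled by its dominance class
and all its trials inherit that label.

## Connectivity

`build_gppi_design()` follows the generalized-PPI variant that forms the
interaction at the hemodynamic level: the seed series is z-scored and
multiplied TR by TR with each condition's HRF-convolved regressor; no
deconvolution is attempted (appropriate for a block design, and the only
variant whose generative counterpart is exactly expressible — which is
what makes zero-noise recovery testable). The physiological regressor and
all interactions enter alongside the full nuisance set.

`partial_spearman()` uses the rank-Pearson first-order partial formula
with average ranks. At the 5-sample windows used here exact tie handling
matters; windows containing any constant series, or a perfect rank
correlation with the conditioning series, are undefined and yield `NA`
(missing, never an error, so sliding series degrade gracefully).
`sliding_partial_correlation()` uses a centred window of 10 s = 5 TRs
(forced odd by construction), Fisher-transforms with |r| clipped at
1 − 10⁻⁷ (the clip constant is recorded as an attribute), and leaves
incomplete edge windows missing. Group comparison of the dynamics is a
per-timepoint paired Wilcoxon on per-subject mean z epochs, aligned with
the same 6-s delay.

The conditioning ("noise") ROI is whatever column the user designates; the
anatomical construction of such a reference region is out of scope at ROI
level.

## The pipeline and its defaults

`run_pipeline()` chains everything deterministically from one master seed
(all sub-seeds are drawn once, up front): schedules → behavioural
simulation → hysteresis table → direction-dominance classification →
BOLD simulation → FFX task contrasts per subject → RFX group tests with
BH-FDR across ROIs → event-related averages → gPPI contrast per subject →
RFX → sliding-window dynamics comparison. Dominance follows the usual
design: a direction is dominant when positive labels form a strict
majority; pairs with exactly one dominant direction contribute that
direction to group A and the other to group B (with a mean-value fallback
if no pair is asymmetric, so the contrast is always defined). Outputs are
BIDS-style TSVs plus a JSON summary; every file carries a sidecar with the
configuration hash, seed and package version, and no timestamps, so
identical configurations are byte-identical. The default study —
17 participants, 3 dynamic + 3 static runs, 280/249 volumes at TR 2 s —
runs in well under a minute on one core.

## Problem sizes and what the tests show

The test suite validates every stage against independent oracles:
brute-force frame-onset scans, residual-rank regression for the partial
correlation, matrix-algebra GLM oracles, `stats::wilcox.test` and
sign-flip permutation for the signed-rank test, and direct-formula checks
elsewhere. Monte-Carlo checks use the default noise model: behavioural
recovery runs 17 observers × 12 trials per cell at injected shifts
{−20, 0, +20} % and requires group means within ±2.5 % (one morph step);
gPPI sign recovery and null false-positive rates use 200 subject-level
(three-run) simulations each. These sizes were chosen as the smallest
that make the binomial bounds meaningful while keeping the suite quick to
run.

Passing tests show the chain is *internally* correct and well calibrated
under the generator's assumptions — linear superposition, a canonical HRF,
AR(1)-plus-drift noise, stationary coupling within condition, an observer
whose static and dynamic judgments share one latent band. They do not show
that real BOLD obeys these assumptions (real noise is neither AR(1) nor
stationary; real HRFs vary regionally; real hysteresis need not displace
both borders equally), and group results on real participants are not
reproduced here in any form.

## Known limitations

* The hysteresis metric uses only the P2 border; paradigms where the
  entry border carries the history effect would need the exported P1.
* The static inflection inherits the 9-frame probe grid's resolution
  (20 % near the category boundaries under the defaults); finer probe
  sets would sharpen it.
* ROI level only: no voxel maps, no spatial preprocessing, no
  deconvolution-based PPI, no reaction-time modelling.
* Negative-hysteresis dominance is representable in the generator
  (negative `h_shift`) but the default study conditions, like the class of
  experiments they emulate, centre on positive dominance.
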