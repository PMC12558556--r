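---
title: "Quantifying locomotion-speed coding in striatal spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locomotion-speed coding in striatal spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedcells)
```

## The problem

A sizeable fraction of striatal neurons — both putative medium spiny
projection neurons (MSNs) and fast-spiking interneurons (FSIs) — fire in
proportion, or in inverse proportion, to how fast an animal is running.
`speedcells` implements the complete analysis chain needed to identify and
characterize such *speed cells* from two raw ingredients: a uniformly
sampled X–Y position track and per-unit spike-time lists, with a trial
table carrying the task structure (cue type, spatial choice, outcome).

Every stage is exposed as an ordinary function; `run_all()` chains them.
Because the real recordings the method was designed around are not
bundled, the package ships a synthetic-session generator with fully known
ground truth, and the test suite and `scripts/acceptance.R` validate the
pipeline against that ground truth.

## From track to paired series

Positions (cm) are smoothed with a centered 5-point moving average
(shrinking window at the edges, so no phase shift), and speed is the
Euclidean displacement between successive smoothed samples divided by the
sampling period (default 0.0256 s), in cm/s. Samples are masked out when
they fall outside trial epochs, when speed is exactly zero, or when it
exceeds 60 cm/s — the latter two being signatures of tracking failure
rather than behavior.

Speed and each unit's firing rate are then averaged in 1-s windows that
advance by 0.1 s (900 ms overlap). Windows are anchored at the start of
each contiguous run of valid samples and never cover a masked sample, so
both series always live on an identical grid; each window keeps the id of
its contiguous segment. Both series are z-scored with the population
(n-denominator) SD, which makes the lagged cross-correlation below exactly
a Pearson correlation coefficient. Units with an in-task mean rate of
0.5 Hz or less are excluded before any scoring (the rate is computed over
trial epochs; whether the original inclusion rule used the whole recording
is unknowable from the description, and the in-task reading is the one the
rest of the analysis is consistent with).

## Speed score, lag, and the surrogate null

For integer stride multiples `k` with |lag| ≤ 5 s, the cross-correlogram
is

r(k) = cor( rate(t), speed(t − k·0.1 s) ),

using only window pairs inside the same contiguous segment, and only lags
with at least 30 pairs. Positive lag means firing-rate changes *follow*
speed changes. The **speed score** is the value of `r` at the lag
maximizing |r| — the signed absolute peak, so strong negative coupling is
reported as a negative score. Ties on |r| resolve to the lag nearest zero,
an exact tie to the more negative lag. The ±5 s search window is a design
choice: reported lags concentrate well inside ±2.5 s, so the window covers
them with margin while keeping the surrogate minimum-shift constraint
easy to satisfy.

The null is built by circularly rotating the z-scored rate series through
the concatenated valid-window sequence by a uniform random 20–50% of the
analyzed length (random direction) and recomputing the full peak, 10,000
times per unit by default. Rotation preserves the rate autocorrelation
while destroying alignment with speed. A unit is a *candidate* speed cell
when its score lies more than 2 surrogate SDs from the surrogate mean; an
empirical two-sided p-value from the same surrogates is BH-adjusted across
units, and the final call requires both the 2-SD rule and adjusted
p < 0.05. Storing both gates separately lets either criterion be reported
on its own. |score| < 0.2, 0.2–0.4 and > 0.4 are labeled weak, moderate
and strong.

A property worth knowing: the signed peak is a maximum over ~100 highly
correlated lags, so its null distribution is concentrated and bimodal
rather than Gaussian. The 2-SD rule is therefore *conservative* — on
gain-0 synthetic units it flags ~1% of units, not the ~4.6% a Gaussian
tail would give — while the empirical p-values from the identical
surrogates are close to uniform. The package reports both so users can
choose the calibrated gate.

## Stability and label modulation

Trials are split into five contiguous near-equal blocks (remainder to the
earliest blocks; fewer blocks, with a warning, when fewer than 55 trials
are available; no block analysis below 22). `subset_speed_score()` redoes
the identical scoring computation restricted to windows whose start lies
in trials of one block, cue, choice, or outcome level; with the full trial
set it reproduces the session score bit-for-bit.

`modulation_test()` asks a different question — whether a unit's mean
firing rate differs between the two states of a task variable, regardless
of speed coupling. The statistic is the difference of per-trial rates
(in-trial spike count over trial duration, on raw spikes; the trial-level
mean needs no binning), and the null permutes whole-trial labels without
replacement, preserving state counts. The 2-SD rule on this single
(near-Gaussian) statistic is well calibrated: ~5% of unmodulated synthetic
units are flagged, and a +3 Hz offset on a 5 Hz unit with 40 trials is
detected essentially always.

## Locomotion bouts and normalized PSTHs

The masked speed is averaged onto a 0.1-s grid within each contiguous
segment and scanned with 7-s windows advancing one sample at a time. An
onset requires all of the first 2 s strictly below 5 cm/s and at least
50% of the following 5 s strictly above it; an offset is the mirror
condition. Samples exactly at threshold satisfy neither. Overlapping
candidates resolve to the earliest and the scan resumes after the accepted
window, so same-kind events are at least 7 s apart; windows never span a
masked gap because they never leave a segment. Time zero (`t_ref`) is the
boundary between the 2-s and 5-s sub-windows. Note a subtlety of the
50%-persistence rule: for an instantaneous step the first qualifying
window begins up to 1 s *before* the step, so `t_ref` can lead the
physical transition; this is inherent to the definition, not jitter.

Each unit's spikes are histogrammed in 0.1-s bins over [−2 s, +5 s) around
every event and divided by that event's own mean rate, so every retained
event contributes a curve with bin-mean exactly 1. Events with zero spikes
in the window have no defined normalization and are excluded, with the
count reported (the alternative — leaving such events unnormalized —
would mix scales across events). The event-average and SEM are returned
together with the matching average speed trace.

## Decoding speed from firing rates

Decoding uses disjoint 1-s bins: overlapping windows would place nearly
identical samples on both sides of a cross-validation boundary. Folds are
10 contiguous, unshuffled temporal segments of near-equal size. Within
each fold's training data the pipeline fits an upper-tail Winsorization
cap (95th percentile, linear interpolation between order statistics) for
each series and feature standardization; both are then applied to the held
-out fold, after which each series is smoothed with a Gaussian kernel
(SD = 1 bin, truncated at ±4 SD, renormalized at segment edges). Features
are per-unit {x, x², x³}; single-unit decoding fits ordinary least
squares, multi-unit decoding fits ridge with penalty 1 on the standardized
features and an unpenalized intercept (cell combinations from one session
are collinear by construction, and the small penalty keeps duplicated
units finite without materially shrinking a single strong predictor).
Accuracy is the mean held-out coefficient of determination, which is
negative when predictions are worse than the test-fold mean. Chance levels
repeat the identical pipeline on circularly shifted rate series (20–50% of
the length, 100 repetitions); for combinations one common shift per
repetition is applied to all members, preserving inter-unit structure
(independent per-unit shifts are available via a flag). Only units with
single-unit accuracy ≥ 0.1 enter combinations of 1–5 cells.

Two pragmatic notes. Because smoothing spans fold boundaries by a few
bins, a strictly leakage-free pipeline would refit it per fold too; the
kernel is local (±4 s) and the effect is negligible at 1-s bins.
Re-estimating the Winsorization percentile on already-capped data moves
the cap slightly, so capping is only exactly idempotent under a fixed
cap — which is the form the CV pipeline uses.

## The synthetic generator

`synth_config()` defaults describe the regime the analysis targets, and
were fixed once from the task description, not tuned to any test:

* **Speed profile**: a semi-Markov alternation of stop (~1 cm/s) and run
  (~20 cm/s) states, mean durations 3 s and 5 s (SD 25%, floor 1 s), with
  Ornstein–Uhlenbeck jitter (τ = 0.5 s, stationary SD 2 cm/s, reflected at
  zero so stationary speeds stay positive). The velocity series is
  integrated along a smoothly wandering heading into a 2-D track sampled
  at 0.0256 s; recomputed speed matches the generated truth to < 5% RMS.
* **Trials**: equal-length trials tiling the session with 1-s gaps; cue
  alternates in blocks of 10, choice is a fair coin, outcome is rewarded
  with probability 0.75 (both states forced to occur at least twice).
* **Artifacts**: mistracking events at 0.5/min, each ~0.2 s of frozen
  position (speed exactly 0) or 90 cm/s jumps (masked as > 60), so the
  masking path is always exercised.
* **Spikes**: exact Poisson thinning against the intensity upper bound,
  with λ(t) = softplus(softplus_inv(baseline) + gain · speed(t − lag) +
  label offsets). The softplus link keeps rates non-negative with smooth
  dependence on speed, so the injected rate–speed correlation is
  controllable; the linearity of real tuning curves is an empirical
  finding the generator does not presuppose. `softplus_inv` makes
  `baseline_rate` the exact rectified rate at zero speed.
* **Tuned units**: a positively tuned MSN-like unit uses baseline 5 Hz
  with gain +0.17 Hz/(cm/s); a negatively tuned unit uses baseline 15 Hz
  with gain −0.22. Both give a true rate–speed correlation of ≈ 0.4, the
  regime the recovery studies require. (With equal baselines a negated
  gain lands the rate in the compressive part of the softplus and inflates
  |r|; suppression needs headroom, which is also the physiologically
  natural picture for negatively modulated units.)

Ground truth (unit parameters, state sequence, true transition times,
artifact-free speed) is returned as a separate object that analysis code
never sees.

What the generator does **not** emulate: maze geometry and place fields,
theta-band or bursty spike-train structure, rule-switch learning dynamics,
or slow drift in excitability. Passing the validation suite therefore
demonstrates correctness of the estimators under Poisson spiking with the
stated speed coupling — not robustness to every failure mode of real
recordings.

## Problem sizes used in validation

The bundled validation runs use sessions of 400–660 s with 24–60 trials,
200 gain-0 units (10 sessions × 20) with 1,000 surrogates each for null
calibration, 36–60 tuned-unit sessions for sign/lag recovery, 20 seeds
for each power-style property, and 100 circular-shift repetitions per
chance-level estimate. These sizes give binomial standard errors of ~1.5
percentage points on the calibration fractions while keeping a full run in
a few minutes; the defaults users see (`n_surr = 10000`,
`n_shuffles = 10000`) match the published procedure instead.

## Numerical choices and degenerate inputs

* Half-open intervals [start, end) everywhere, so boundary spikes count
  once.
* Peak ties: nearest-zero lag, then the more negative lag.
* Lags with fewer than 30 within-segment pairs are dropped; a unit with no
  usable lag, a zero-variance series (silent unit), or a zero surrogate SD
  raises a degenerate-unit error that `score_session()` converts into an
  exclusion row with the reason.
* Subsets with too few windows yield `NaN` scores with an attached reason
  rather than failing the session.
* Zero-spike PSTH events are excluded and counted; an all-excluded PSTH
  returns `NULL`.
* The pixel→cm calibration of a tracking system is never assumed; raw
  pixel tracks require `pixels_per_cm` at read time.

## Known limitations

* The 2-SD classification gate is conservative for the peak statistic (see
  above); relative comparisons between populations are unaffected, but
  absolute speed-cell fractions from the 2-SD gate alone will undercount
  relative to a calibrated test.
* Bout `t_ref` can precede the physical transition by up to 1 s under the
  50%-persistence rule.
* Overlapping 1-s windows make neighboring speed-score samples strongly
  dependent; all inference here goes through surrogates, which carry that
  dependence, but the binned series should not be fed to methods assuming
  independent samples.
* Decoding assumes the rate–speed map is static within a session; the
  stability tools quantify, but the decoder does not model, drift.
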