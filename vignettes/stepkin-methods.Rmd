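---
title: "Methods: smartphone estimation of 2MST thigh kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone estimation of 2MST thigh kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepkin)
```

## The measurement problem

During a 2-Minute Step Test a participant marches in place for 120 s. A
smartphone held against the anterior thigh records tri-axial angular
velocity at a nominal 60 Hz, while two reflective markers (greater
trochanter, lateral femoral condyle) tracked by an optical system provide
a reference measurement of the same thigh segment. The quantity of
interest is the peak thigh angular velocity of each step cycle,
ω_peak (deg·s⁻¹), together with the outcome variables derived from the
per-cycle table: step count, cycle duration, cadence, rate of performance
change, and coefficients of variation.

The raw phone stream is not directly usable: its sampling clock jitters
between roughly 58 and 62 Hz, occasionally stamps two samples with the
same time, drifts slowly, mixes anatomical axes (crosstalk from
sensor-to-segment misalignment), compresses large amplitudes, and is
offset from the reference clock by an unknown constant lag. `stepkin`
implements two estimation pipelines on top of a common preprocessing
layer, and an agreement layer to validate them.

## Preprocessing

**Resampling.** Samples sharing a timestamp are collapsed to their mean —
unbiased under symmetric noise, unlike keeping the first or last. A cubic
spline through the distinct timestamps is evaluated on a uniform 60 Hz
grid anchored at the first timestamp; the grid never extends past the
last raw timestamp because cubic splines extrapolate badly. Fewer than 4
distinct timestamps is an error (the cubic spline is undefined).

**Drift.** The slow sensor bias is removed by subtracting a zero-lag
2nd-order Butterworth low-pass baseline at 0.1 Hz — at least a decade
below plausible stepping frequencies (0.9–1.5 Hz), so stepping content is
untouched. The signal is mean-centred before filtering, which makes a
constant signal map exactly to zeros, and the residual mean is removed so
the record is zero-mean. There is no standard definition of "drift
correction" for phone gyroscopes; this high-pass-equivalent construction
is the package's choice.

**Signs.** The device axis map multiplies each channel by ±1 so that
thigh elevation is positive, matching the reference convention. Applying
a map twice restores the input.

**Zero-lag filtering.** Every Butterworth filter in the package runs
forward and backward, squaring the magnitude response
(|H(f)|² = 1/(1 + (f/f_c)^(2n)) for order n) and cancelling phase shift —
phase distortion would bias peak timing, which is half of what the
package measures. The marker-coordinate filter (6 Hz, order 2) is applied
zero-lag for the same reason. R's `signal::filtfilt` applies no edge
padding, so the implementation first extends the signal by odd
reflection (the convention used by scipy): an odd reflection continues a
ramp linearly, which keeps the very low 0.1 Hz drift baseline
well-behaved at the record ends. The padding length is
`3·order + ceil(6·rate/cutoff)` samples, capped at the signal length.

## Reference kinematics

The thigh angle is measured from the downward vertical:
`atan2(horizontal, −vertical)` of the hip→knee vector, so 0° = thigh
vertical, 90° = thigh horizontal with the knee anterior, and a raised
knee gives a positive angle. The choice "knee anterior = positive" makes
elevation velocity positive, consistent with the phone convention. The
angle is invariant to translating both markers and to scaling the
segment length.

Occlusion gaps are spline-filled; gaps longer than 10 frames are filled
too but flagged with a warning, since gap filling becomes unreliable for
long occlusions. Angular velocity is the first derivative of the angle:
central differences in the interior (gain sin(ω∆t)/(ω∆t), within 1% of
unity for 1 Hz content at 60 Hz), one-sided at the ends.

## Peak detection

One positive (elevation-phase) peak per step cycle. Candidates are strict
local maxima above a height floor and a prominence floor; a greedy pass
in descending height order (ties to the earlier peak) enforces the
minimum separation, so when two candidates are too close the larger
survives. The parameters are physiological, not tuned:

| parameter | default | rationale |
|---|---|---|
| `min_separation` | 0.40 s | cadence ≤ ~150 cycles·min⁻¹ per leg |
| `min_height` | 30% of the series' 95th percentile | genuine peaks stand far above noise; scale-free |
| `min_prominence` | `min_height / 2` | rejects shoulder bumps on pulse flanks |

The detector is verified against a brute-force oracle (enumerate all
strict local maxima, filter, greedy selection with plain loops) on
hundreds of random smoothed series. Peak values can optionally be refined
by the vertex of the parabola through the three samples around the
maximum; the refined value is never below the sampled one, and a flat
triple returns the sample unchanged. The reference pipeline uses the
refinement (its targets feed the ML stage); the analytical pipeline
reports raw sampled peaks.

## Analytical pipeline

A 10 s moving window advancing by 9 s (1 s overlap) — the only reading
consistent with "10 s window, 1 s overlap" — is classified by its
dominant cycle frequency f_d: the maximum-magnitude bin of the
mean-centred real FFT, 0 Hz excluded, ties broken toward the lower
frequency. Per window, each candidate cutoff on the 1–12 Hz grid (0.1 Hz
steps — finer than any plausible sensitivity of the criterion) filters
the phone window, and the cutoff minimizing the RMS error against the
time-synchronized reference window is that window's optimum; ties within
machine tolerance break toward the lower (smoother) cutoff. A
least-squares line through the pooled (f_d, optimal cutoff) pairs is the
cutoff map, applied with clamping to [1, 12] Hz. If every window shares
one f_d the fit is singular and a constant map (median optimum) is used.

At deployment the map is fixed: each window is filtered at
`clamp(a·f_d + b)`, overlapping regions are merged by a linear crossfade
(continuous output, no amplitude doubling; exact wherever neighbouring
windows agree), a trailing partial window reuses the last full window's
cutoff (frequency resolution on short segments is too poor to estimate
f_d), and a window with undefined f_d (constant content) reuses the
previous cutoff. Output length always equals input length.

Synchronization maximizes the normalized cross-correlation over integer
sample lags within ±2 s; a peak correlation below 0.2 attaches a
low-confidence warning. Synchronization precedes map fitting because the
RMS criterion compares samples pairwise.

## ML pipeline

Features are extracted from ±0.12 s windows (7 samples each side at
60 Hz, the symmetric window fully inside ±0.12 s) of all three
6 Hz-prefiltered axes, centred at each reference peak — the reference
peak detected on the x axis anchors all axes. Windows clipped by the
signal edge are dropped with a logged count. Per axis: window peak;
10/25/50/75/90th percentiles (a standard five-number spread; the set is
configurable); mean; SD; RMS; signal energy Σv²·∆t (discretization-
stable); high-amplitude width — time above 50% of the window peak, the
common duration-at-half-maximum convention; zero-crossing count; and the
parabolically interpolated peak. The cycle duration is copied from the
anchor table.

The stack combines a linear elastic-net (behind median imputation,
near-zero-variance filtering and standardization) with histogram
gradient-boosted regression trees. Folds are subject-disjoint —
leave-one-subject-out logic, capped at K = min(subjects, 10) — and the
ridge meta-learner is fitted only on out-of-fold base predictions, so no
base learner ever scores its own training subjects. The bases are then
refitted on the full training partition. Isotonic calibration
(non-decreasing map, out-of-range queries clipped to the training range)
and the tail correction are fitted on the out-of-fold stacked
predictions rather than in-sample refit predictions, which keeps both
post-processors honest about generalization error. The tail correction
regresses targets on calibrated predictions above the 95th percentile of
the calibrated training predictions and applies only above that
threshold; with fewer than two tail pairs (or a degenerate tail) it
disables itself to the identity.

All fitting randomness (fold assignment, internal cross-validation folds,
tree fitting) derives from the seed recorded in the model's provenance,
and predictions are deterministic given a fitted model. The ML path
re-estimates only the peak magnitude: anchor times and durations pass
through unchanged, so cycle count and duration are identical to the
anchor set by construction.

**Anchoring at deployment.** Without a reference recording there are no
reference anchors; the supported extension is to anchor at the peaks of
the adaptively filtered phone x axis and let the model refine the
magnitudes. This mode is distinct from the evaluation protocol and is not
used in any validation here.

## Evaluation protocol and data partitioning

`replicate_study()` partitions *subjects* 70/30: the cutoff map is fitted
on windows pooled over training subjects, the stacked model on training
subjects' cycles, and both pipelines are evaluated on the held-out
subjects only. A cycle-level 70/30 partition (`split_cycles()`) is also
implemented and enforced via recorded test keys — any fitting call that
sees a test cycle raises a leakage error — but the cohort evaluation uses
the subject-wise split deliberately: 10 s analysis windows straddle many
cycles, so a cycle-level partition cannot keep window-level map fitting
free of test-cycle influence, whereas a subject-wise split is airtight at
every granularity. `run_analytical()` additionally refuses to evaluate a
subject recorded in the map's fit provenance.

Agreement is summarized by Bland–Altman reports: bias (mean difference),
sample SD of differences, limits of agreement bias ± 1.96·SD (normal-
theory 95% limits), a proportional-bias regression of differences on pair
means, and the correlation of absolute residuals with pair means as a
heteroscedasticity indicator. Differences are oriented
reference − estimate, so a pipeline that underestimates shows positive
bias; the orientation is stored in every report.

## The synthetic generator

Each cycle is a raised-cosine elevation pulse θ(t) = θ_max/2·(1 − cos 2πt/T):
smooth, essentially band-limited, and with closed-form angular velocity —
a single sine period of amplitude ω_peak = π·θ_max/T peaking at T/4.
Ground-truth peaks come from this pulse calculus, never from peak-picking
on sampled data, so the generator is a valid oracle for every pipeline.
Durations are truncated-normal (≥ 0.4 s) and the per-cycle peak follows a
linear first-to-last trend plus noise; θ_max is derived per cycle as
ω·T/π, parameterising the generator directly in the units the outcomes
are reported in.

The phone channel model applies, in order: gain; saturating compression
v → v/(1 + κ|v|/300) with κ = 0.10 by default — a mild ~9% loss at
300 deg·s⁻¹, placed in the observed peak range by the 300 deg·s⁻¹
scale constant; crosstalk fractions (6%, 3%) into y and z; additive noise
(SD 8 deg·s⁻¹); a drift ramp (3 deg·s⁻¹ per minute); timestamp jitter
(SD 2 ms, intervals clipped to ±50% of nominal), duplicate stamps
(probability 0.01), a constant inter-device lag (0.18 s); and a flipped
device x axis that the reader's axis map undoes. The phone records 1 s of
padding before and after the test, as a real operator would start the
recording before the test begins. Marker noise is 1 mm.

Cohorts draw per-subject parameters from population distributions of
healthy adults performing the 2MST: subject mean ω_peak ~ N(303, 39)
deg·s⁻¹ clipped to [204, 444]; mean cycle duration ~ N(0.84, 0.11) s
clipped to [0.65, 1.06]; within-subject duration CV ~ N(3.9, 1.6)%;
within-subject peak CV fixed at 5%; and a 40/40/20
steady/descending/ascending mixture of trends (steady ~ N(0, 4);
descending ~ N(−25, 4) capped at −20; ascending ~ N(33, 5) floored at
25 — centred so the realized edge-window RPC lands near ∓7% of the mean
peak, with margins that keep the realized class consistent with the
configured one for nearly all subjects).

**What the generator does not emulate.** Soft-tissue artifact with its
own dynamics (modelled only as stationary noise plus static crosstalk),
hand-tremor of the held phone, non-sagittal thigh motion, marker
occlusion bursts correlated with pose, magnetometer/accelerometer fusion
artifacts, and between-cycle correlation of durations beyond the linear
trend. Passing tests on synthetic cohorts therefore demonstrates the
pipelines' correctness and their relative behaviour under the modelled
defects — not field accuracy on any particular device.

## Numerical choices and degenerate inputs

- Cutoff-grid RMS ties break toward the lower cutoff; FFT-bin ties toward
  the lower frequency; greedy peak ties toward the earlier peak. All
  deterministic.
- The parabolic vertex with a zero second difference returns the sampled
  peak unchanged.
- An all-zero or sub-threshold series yields an empty cycle table (the
  caller decides severity); an empty phone signal yields an empty AA
  table.
- A constant segment has no dominant frequency: an error where the user
  asked for it directly, a reuse of the previous window's cutoff inside
  the adaptive filter (so DC passes any map unchanged).
- CVs with zero mean and RPC with an empty edge window are NA with an
  explicit flag rather than infinities.
- Writers print `%.17g` so read-backs are bit-exact; JSON reports use 17
  significant digits.
- Seeds: every stochastic operation (generator, cohort, splits, folds,
  boosting) takes an explicit seed; derived per-session seeds are drawn
  below 2³¹.

## Problem sizes

The validation cohorts used by the test suite and the acceptance script
are sized for a laptop: 20 subjects (≈ 2 900 cycles, 14 train / 6 test)
for the pipeline-comparison study, 50 subjects for population-recovery
checks, 200 subjects for the strategy-mixture check, and 200 random
series for the detector-vs-oracle equivalence. These sizes give the
directional comparisons comfortable margins while keeping a full run in
tens of seconds.

## Known limitations

- The AA evaluation reports raw sampled peaks; sub-sample refinement
  would change its bias by well under the compression-induced bias.
- Isotonic calibration clips out-of-range queries, so the ML pipeline
  cannot extrapolate above the largest calibrated training prediction
  except through the tail correction.
- The cutoff map is global per study; per-subject maps might track
  idiosyncratic cadence better but would need per-subject reference data
  at deployment.
- `RPC` is reported as an edge-mean difference in deg·s⁻¹ — the units of
  its classification band — with the per-second slope as an auxiliary
  field; treating it as a pure slope would change the classification
  threshold's meaning.
- Sagittal-plane projection assumes stepping is predominantly
  flexion–extension; strongly abducted gait would violate the two-marker
  planar model for phone and reference alike.
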