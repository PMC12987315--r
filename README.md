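# stepkin

Smartphone-based assessment of the 2-Minute Step Test (2MST).

The 2MST — marching in place for 120 s, lifting the knees to a standardized
height — is traditionally scored by counting steps, which says nothing about
*how* the test was performed. `stepkin` turns a thigh-held smartphone
gyroscope recording into per-cycle kinematic outcomes, validated against a
two-marker optical motion-capture reference, for researchers and clinicians
instrumenting functional fitness tests with wearable sensors.

## What it computes

For each step cycle the central quantity is the peak thigh angular velocity
ω<sub>peak</sub> (deg·s⁻¹). From the cycle table the package derives:

- **STP** — number of step cycles (count of detected ω<sub>peak</sub>);
- **DUR** — cycle duration, the time between successive ω<sub>peak</sub>;
- **cadence** — cycles·min⁻¹ over the nominal test duration;
- **RPC** — rate of performance change: mean ω<sub>peak</sub> of the final
  20 s minus the initial 20 s, classified *steady* (|RPC| ≤ 11.5 deg·s⁻¹,
  boundary inclusive), *ascending* or *descending*;
- **CV<sub>ω</sub>, CV<sub>DUR</sub>** — coefficients of variation
  (100·SD/mean) across cycles.

Two competing pipelines estimate ω<sub>peak</sub> from the phone:

1. **Analytical approach (AA).** The x-axis (thigh flexion–extension) is
   filtered by an adaptive zero-lag 2nd-order Butterworth low-pass whose
   cutoff tracks the dominant cycle frequency f<sub>d</sub> of a 10 s moving
   window (1 s overlap) through a fitted linear map
   f<sub>c</sub> = a·f<sub>d</sub> + b, clamped to 1–12 Hz. The map is
   trained by an RMS criterion: for each window the candidate cutoff
   (1–12 Hz in 0.1 Hz steps) minimizing the RMS error against the
   motion-capture reference is that window's optimum. Peaks of the filtered
   signal are the AA estimates.
2. **Machine-learning approach (ML).** Time-domain features (peak,
   percentiles, mean, SD, RMS, energy, high-amplitude width, zero
   crossings, parabolic-interpolated peak, cycle duration) are extracted
   from ±0.12 s windows of all three 6 Hz-prefiltered axes, anchored at
   reference peaks. A stacked regression — elastic-net and histogram
   gradient-boosted trees under a ridge meta-learner fitted on
   subject-disjoint out-of-fold predictions — is calibrated by isotonic
   regression and finished with a linear correction of the top-5% tail.

Method agreement is quantified by Bland–Altman analysis (bias, 95% limits
of agreement `bias ± 1.96·SD`, proportional-bias regression), oriented
reference − estimate so positive bias means the phone underestimates.

A synthetic paired-session generator (`simulate_session()`,
`default_cohort()`) renders phone + marker recordings from closed-form
raised-cosine elevation pulses with known per-cycle ground truth, plus the
defects real sensor logs show: 58–62 Hz timestamp jitter, duplicate
stamps, noise, drift, axis crosstalk, saturating amplitude compression and
a constant inter-device lag. Every stage of the package is testable
against it without any instrument data.

## Worked example

```r
library(stepkin)

sess <- simulate_session(session_spec(), seed = 42)    # one 120 s session
p <- prepare_session(sess$phone, sess$markers)         # resample, sync, reference
p$sync
#> <sync_result> lag 1.1833 s, peak correlation 0.999

p$ref_cycles
#> <cycle_set> 143 cycles [reference], test duration 120 s
#>   omega_peak 300.7 +/- 14.1 deg/s; mean DUR 0.839 s

summarize_cycles(p$ref_cycles)
#> <outcome_summary> [reference] STP 143, cadence 71.5 cycles/min
#>   DUR 0.839 +/- 0.042 s (CV 5.0%); omega_peak 300.7 +/- 14.1 deg/s (CV 4.7%)
#>   RPC 4.6 deg/s -> steady (band +/- 11.5)

aa <- run_analytical(p$phone, constant_cutoff_map(6), test_duration = 120)
pairs <- pair_cycles(p$ref_cycles, aa)
bland_altman(p$ref_cycles$omega_peak[pairs$a], aa$omega_peak[pairs$b],
             labels = c("reference", "AA"))
#> <agreement_report> reference - AA (n = 143)
#>   bias 25.82, 95% LoA [17.43, 34.22] (sd_diff 4.28)
#>   proportional bias slope 0.1513 (p = 7.49e-09)
```

Reading the output: the cross-correlation recovers the 1.18 s inter-device
offset; the reference finds 143 cycles (cadence 71.5 cycles·min⁻¹) with a
steady pacing profile; and the analytical pipeline, run here under a fixed
6 Hz cutoff, underestimates ω<sub>peak</sub> by ~26 deg·s⁻¹ on average
because of the phone channel's saturating amplitude compression — the bias
the ML pipeline is designed to remove. The full protocol (70/30 subject
split, cutoff-map fitting, stacked-model training, held-out agreement) is
one call: `replicate_study(default_cohort(20, seed = 1), seed = 1)`.

A command-line wrapper with subcommands (`simulate`, `reference`,
`aa-fit`, `aa-run`, `ml-train`, `ml-predict`, `outcomes`, `agree`,
`replicate-paper`) is installed at `inst/cli/stepkin`; see
`?run_command`.

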