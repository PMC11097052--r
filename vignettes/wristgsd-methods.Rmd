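---
title: "Detecting gait sequences from wrist-worn accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait sequences from wrist-worn accelerometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristgsd)
```

## The problem

Long free-living recordings from a wrist-worn triaxial accelerometer contain
minutes of walking buried in hours of rest and non-gait arm activity.
Before any spatiotemporal gait parameter can be estimated, the *gait
sequences* (GSs) — continuous walking intervals with a start and end time —
must be located. The wrist is a hard place to do this: the sensor's axis
orientations change constantly with free arm movement, arm swing varies in
amplitude between people and strides, and the arms do many things besides
swinging. `wristgsd` implements a family of norm-based GS detectors together
with the complete validation machinery needed to benchmark them against
reference annotations, plus a synthetic-signal generator so that the whole
pipeline is testable without access to any proprietary recording.

Two conventions run through every module:

* **Orientation independence.** Every detector consumes the per-sample
  Euclidean norm of the three axes (or, where the original method was
  axis-specific, a norm-based replacement). A fixed rotation of the raw
  samples leaves the five purely norm-based detectors' output bit-identical;
  the two detectors that are not purely norm-based (one estimates a vertical
  axis, one rectifies per axis) agree within one analysis window.
* **Units are g throughout.** All thresholds are in units of gravitational
  acceleration; published parameter values are used as printed, and the
  parameter banks ship in `inst/params/parameter_banks.yaml`.

## Interval model and the assembly rule

GSs are half-open intervals `[start_s, end_s)` in seconds from the start of
the recording; a GS list is sorted and strictly separated. All detectors
reduce to either *step events* (time points) or *stride intervals*, which
`assemble_gs_from_events()` merges under one rule: two events belong to the
same GS when they are **not further apart than 3 seconds** (end-to-next-start
for strides, time-to-time for steps). Runs with fewer than `min_events`
events are discarded; the defaults are 3 for steps and 2 for strides, a
stride contributing its two boundary contacts, so a single clean stride
already forms a (two-event) sequence while isolated step detections do not.
A GS built from steps ends at the last step time — no padding is added,
because no padding rule is published.

## The detectors

| key | idea | default → wrist-optimized parameters |
|-----|------|--------------------------------------|
| `paraschiv2019` | peaks of the detrended, low-passed norm above `th`, assembled to GSs | `th` 0.1 (0.15 for the stricter lower-back variant) → 0.35 |
| `paraschiv2020` | as above with iterative smoothing/enhancement and a data-adaptive threshold | not tuned (adaptive) |
| `iluz` | convolution with a one-period sine gait template, variance-gated maxima | `activity_thres` 0.01→0.04, `min_bout_length` 5→10 s, `template_len` 0.5→1 s, `cm_norm_thres` 0.4→2.5 |
| `gu` | block maxima of the norm filtered by magnitude, amplitude similarity and periodic continuity | `verisense_k` 3→2, `sim_thres` −0.5→−0.8, `cont_thres` 4, `mag_thres` 1.2 |
| `karas` | adaptive template matching: correlation of rescaled stride patterns over a duration grid | `sim_MIN` 0.85→0.3, `dur` 0.8–1.4→0.2–3.0 s, `ptp_r` 0.2–2.0→0.2–3.0 g |
| `hickey` | 0.1-s windows gated by combined 3-axis SD (moving) and vertical mean (upright) | `ThresholdStill` 0.2, `ThresholdUpright` −0.5 |
| `kheirkhahan` | actigraphy counts per 1-s epoch against an adaptive level, windowed vote | walking threshold 0.75→0.6 |

One-line published descriptions under-determine each original method, so
each detector is specified here as a concrete, testable pipeline faithful to
its description, with every interior constant exposed as an argument:

* minimum step-peak separation 0.25 s (`paraschiv2019/2020`, the debounce in
  `gu`);
* plausible inter-step periodicity band 0.25–2.0 s (`gu`);
* duration grid step 0.05 s and greedy non-overlap resolution, highest
  similarity first with earlier onset on ties (`karas`);
* zero-phase low-pass at 3.5 Hz before peak picking
  (`paraschiv2019/2020`).

Design choices worth flagging:

* **`hickey`'s uprightness gate.** The printed `ThresholdUpright = −0.5` is
  applied to (estimated vertical − 1 g), i.e. the gate passes whenever the
  projection onto the low-passed gravity direction exceeds 0.5 g. At the
  wrist "upright" is poorly defined, so the printed value acts as a
  permissive gate; the movement gate (combined SD > 0.2 g over 0.1 s) does
  the real work.
* **`paraschiv2020`'s enhancement.** The published description calls for
  iterated smoothing and signed-square enhancement with a data-adaptive
  threshold. A literal signed square shrinks sub-unit amplitudes (and two
  iterations fourth-power them), which would defeat any fixed floor, so the
  enhancement used here is the amplitude-normalized signed square
  `sign(x)·x²/rms(x)`: it sharpens peaks relative to the background while
  preserving the signal's scale. The threshold is then
  `max(adapt_floor_g, quantile_0.1(permissive-pass peak heights))`; the
  0.05 g floor keeps rest-only recordings empty.
* **`kheirkhahan`'s adaptive level.** The original adaptive mechanism is
  unpublished; the stand-in is the median of the recording's nonzero epoch
  counts. For this to behave sensibly the count dead-band must sit at the
  sensor noise floor (2 mg here): rest epochs then produce small nonzero
  counts, the median sits at the noise level, and the window-vote thresholds
  (0.75 default, 0.6 optimized — both deliberately above 0.5) reject rest,
  where only ~half the epochs exceed the median, while accepting gait. With
  a large dead-band rest counts collapse to exactly zero, the median jumps
  to the *gait* median and the printed thresholds could never fire.
* **`karas` templates and matching scale.** Empirical wrist templates are
  not published, so the defaults are a one-period sine and a
  sine-plus-step-harmonic mixture, standardized per duration. As in the
  original adaptive-empirical-pattern method the norm is smoothed (0.15 s
  moving average) before correlation. One consequence is worth
  understanding: in wrist-like signals the norm's dominant cycle is the
  *step* (the harmonic and the heel-strike transients beat the stride
  fundamental), so the best-correlating window length settles near the step
  period (~0.5 s at a 1 s stride), not the stride. The detector is run for
  gait detection, where this makes no difference after assembly; consumers
  of the per-stride output (`attr(gs, "strides")`) should expect step-scale
  segments on step-dominant signals.

## Validation metrics

Detected and reference GS lists are compared on a fixed 0.1-s window grid
starting at 0; a window is gait iff its **midpoint** lies inside a GS (for
half-open windows against half-open intervals this is equivalent to a
≥50 %-overlap rule, and it is unambiguous). Windowed TP/FP/TN/FN yield
sensitivity, specificity, PPV and accuracy; ratios with zero denominators
are `NA` and are excluded from group means rather than zero-filled, which
would bias aggregates. GS count and total-duration errors are expressed
relative to the reference, in percent, with absolute variants.

Group-level aggregation adds:

* **ICC(2,1)** — two-way random effects, absolute agreement, single measure
  — between detected and reference total GS duration across a group's
  subjects, with reliability bands poor < 0.50 ≤ moderate < 0.75 ≤ good
  < 0.90 ≤ excellent (boundary values go to the higher category; the
  published wording leaves boundaries open).
* **Performance index** in [0, 1]: a weighted sum of five benefit metrics
  (accuracy, sensitivity, specificity, PPV, ICC) and two cost metrics (the
  duration and count relative absolute errors, capped at 100 % and
  inverted). The published weighting scheme is in unpublished supplementary
  material, so the default is uniform over the seven metrics (a duplicated
  metric in the published list is treated as a typo); any scheme in the same
  layout can be passed instead. The cap keeps the index bounded as stated.
* **Paired comparisons**: two-sided paired t tests per metric with
  Benjamini–Hochberg adjustment. Zero-variance differences are flagged
  degenerate (p = 0 for a nonzero constant shift, `NA` for identical
  vectors) rather than fed through the t formula.

Grid-search tuning (`grid_search()`) evaluates every parameter combination
over an annotated corpus, pools all recordings into one group and ranks by
the performance index (the selection criterion used when the printed
optimized parameters were derived); a sensitivity-at-fixed-specificity
objective is provided as an alternative, since in practice high specificity
is the binding constraint for downstream gait-parameter estimation. Failing
combinations score −Inf and are logged. Ties break to enumeration order, so
searches are reproducible bit for bit.

## The synthetic world

`generate_recording()` builds signals from a stated, seeded world; every
claim a green test makes is a claim about this world.

* **Gravity and drift.** A unit gravity vector rotates slowly about a random
  fixed axis (0.01 rad/s default) — enough to break axis-specific logic,
  as free arm posture does, while keeping the norm exactly orientation-free.
* **Arm swing.** During gait the swing acceleration points 20° off the
  gravity axis and follows a stride-cycle waveform with a stride-frequency
  component and a *dominant* step-frequency harmonic
  (0.6 sin θ + 0.9 cos 2θ, normalized so the combined peak equals
  `swing_amp_g`, reached once per step). Per-stride amplitude jitter
  (CV 0.1) models cycle-to-cycle variability.
* **Heel-strike transients.** Each step carries a raised-cosine impact pulse
  (width 0.12 s, amplitude equal to the swing amplitude, directed along
  gravity). Real wrist recordings are dominated by such transients; without
  them a smooth oscillation of realistic amplitude would have almost no
  energy in short-window standard deviations and the windowed-SD detector
  could never open its 0.2 g gate.
* **Noise.** White, per axis: 0.08 g during gait (tissue vibration and jerk),
  0.005 g at rest, 0.02 g during arm activity.
* **Arm activity.** Band-limited (0.3–3 Hz) Gaussian bursts with a slow
  on/off envelope, amplitude comparable to gait but aperiodic — a
  stress-test stand-in, not a model of any real activity distribution.
* **Walking aids.** Bilateral mode multiplies swing, impacts and gait noise
  by 0.15 (noise floored at rest level): an arm resting on a rollator
  transmits only attenuated body accelerations. This reproduces, in
  simulation, the qualitative finding that bilateral aid users show markedly
  lower wrist-based detection sensitivity. Note that an amplitude-adaptive
  detector legitimately retains much of its sensitivity under uniform
  suppression — the drop is large for fixed-threshold detectors and small
  (but still present) for the adaptive one.
* **Cohorts.** `make_validation_corpus()` draws per-subject schedules from
  six cohort profiles (healthy older adults through hip-fracture recovery)
  that differ in bout count, bout duration, swing amplitude and cadence,
  mirroring the qualitative ordering seen in free-living studies: impaired
  cohorts walk less, slower, weaker and in shorter bouts.

What the generator does **not** emulate: multi-axis gait harmonics beyond
the first, asymmetric left/right arm swing, posture transitions, sensor
saturation or calibration error, and any realistic taxonomy of non-gait arm
activities. A detector that is perfect here can still fail on real data;
the harness establishes correctness of the pipeline and the *relative*
behavior of detectors under controlled degradations, not clinical accuracy.

Scheduled segment durations are realized on the sample grid (the corpus
generator snaps them to 10 ms at 100 Hz), so scheduled gait time is conserved
exactly in the truth annotation, and truth from back-to-back gait segments is
merged into one sequence.

## Numerical choices

* **Filtering** is zero-phase by construction: the Butterworth *magnitude*
  response is applied in the frequency domain after reflection padding
  (there is no IIR filter-design dependency in the environment). Zero phase
  matters because detected event times must not be shifted by filtering; a
  symmetric pulse keeps its peak location to within one sample.
* **Moving statistics** use shrinking windows at the edges, preserving
  length; cumulative-sum implementations keep everything O(n).
* **Degenerate inputs**: empty event lists assemble to empty GS lists (not
  errors); unsorted events are contract violations; rest-only recordings
  yield empty detections for every detector; undefined metric ratios
  propagate as `NA` and are excluded from means; ICC requires n ≥ 3 and is
  `NA` for smaller groups; numerically-zero-variance paired differences are
  flagged degenerate.
* **Determinism**: one seed per simulated recording with a fixed draw order;
  corpus generation pre-draws per-subject seeds so recordings are
  independent of each other's internals. CLI tables are written at six
  significant digits so identical configurations reproduce byte-identical
  files.

## Known limitations

* The performance-index weights are a uniform stand-in; rankings under the
  original (unpublished) weights may differ.
* The activity-count reconstruction approximates a proprietary algorithm;
  absolute count values are not comparable to vendor output, only their
  within-recording structure is used.
* `karas` is the slowest detector (a correlation per duration-grid point per
  template); on 2.5-hour recordings expect minutes, not seconds.
* The walking-aid simulation suppresses amplitude only; real bilateral-aid
  gait also changes temporal structure in ways the generator does not model.
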