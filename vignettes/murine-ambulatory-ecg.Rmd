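---
title: "Murine ambulatory ECG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Murine ambulatory ECG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambecg)
```

## The problem

Long-term ambulatory electrocardiography (AECG) in freely moving mice
produces hours to days of multi-lead signal at heart rates of 500-750 bpm
(RR intervals of roughly 80-120 ms) with a QRS complex only about 10 ms
wide. Human-oriented tooling, tuned to ~1 Hz heart rates and ~80 ms QRS
complexes, filters away exactly the frequency band in which the murine QRS
lives. This package implements a processing chain adapted to the murine
signal: pre-processing that isolates the QRS band, automatic R-peak
detection, extraction of heart rate, mean RR interval and a
histogram-based heart-rate-variability (HRV) statistic, semi-automatic
flagging of ectopic beats, and quantitative evaluation of detector output
against reference annotations. A synthetic murine ECG generator with exact
ground truth makes every stage testable without animal recordings.

## The processing chain

Each analysed lead passes, in order, through:

1. **Zero-phase high-pass** — a 2nd-order Butterworth filter, cut-off 5 Hz,
   applied forward and backward so that the phase response cancels.
   This removes baseline wander (respiration, movement) without moving the
   R peak in time. Forward-backward filtering uses odd (point-reflected)
   edge padding of three times the filter order and steady-state
   initialisation, so a constant input maps to zero output exactly and no
   start-up transient contaminates the edges.
2. **Decimation** — plain down-sampling from the acquisition rate
   (2000 Hz by default) to a working rate of 1000 Hz, keeping every k-th
   sample. No separate anti-aliasing filter is applied: the next stage is
   a hard band-pass that bounds the aliased energy reaching detection.
   Decimation is restricted to integer factors.
3. **Hard FFT band-pass, 100-200 Hz** — the signal is transformed,
   every bin with folded frequency outside [100, 200] Hz is zeroed, and
   the signal is transformed back. This band isolates the murine QRS at
   the 1000 Hz working rate while rejecting motion artifacts, baseline
   remnants and EMG-band noise. The brick-wall mask makes the operation
   exactly idempotent. When the upper corner exceeds Nyquist (working
   rates below 400 Hz) it is clipped to Nyquist with a warning rather
   than rescaled — the corner frequencies are properties of the murine
   QRS, not of the sampling rate.
4. **Zero-phase derivative** — the central difference
   `(x[i+1] - x[i-1]) * rate / 2` with replicated edges. The symmetric
   kernel has exactly zero phase, so the slope signal stays aligned with
   the band-passed trace.

The chain returns two traces: the band-passed trace (what the reviewer
sees, and where final peak positions are anchored) and the *detection
trace* used by the R-peak detector.

### Units of the detection trace

The peak-height threshold is stated in mV, but a derivative has units of
mV/s, so a units convention is required. The detection trace is defined as
the zero-phase *half central difference* `(x[i+1] - x[i-1]) / 2` of the
band-passed trace — plain millivolts per sample step. Two consequences
motivated this choice:

* the default 0.05 mV threshold then sits far below the detection
  amplitude of a genuine murine R wave (about 0.2 mV for a 1 mV R peak at
  the 1000 Hz working rate), so clean beats always qualify;
* it sits well above the oscillatory tails that the brick-wall band-pass
  attaches to each QRS (about 13% of the beat's detection peak in the
  worst case, i.e. below 0.03 mV). These tails decay like 1/t and
  occasionally superpose coherently between two beats; an absolute
  threshold in these units excludes them categorically, which a threshold
  proportional to the local peak would not.

## R-peak detection

Candidates are local maxima of the detection trace at or above the
height threshold (default 0.05 mV). Candidates closer together than the
minimum peak distance (default 50 ms, a murine refractory bound) are
resolved greedily from the highest candidate down; equal heights keep the
earlier peak, a deterministic tie-break. Each surviving candidate is then
moved to the nearest local maximum of the band-passed trace within a
±10 ms refinement window, so reported positions coincide with the
waveform the reviewer inspects. Because refined positions sit at
band-passed maxima — where the derivative crosses zero — the
minimum-distance constraint is re-checked after refinement using the
candidates' *original* detection heights; re-reading heights at the
refined positions would rank true beats at essentially zero and let
spurious candidates displace them.

Thresholds are configuration values, never hard-coded; the defaults
(50 ms, 0.05 mV) were determined empirically for murine recordings.

## Rhythm statistics

* **Heart rate**: detected peak count divided by recording time (bpm).
  Partial trailing fragments use their true duration.
* **RR intervals**: successive peak differences in ms, each anchored at
  the terminating peak.
* **FWHM heart-rate variability**: RR intervals are binned at 1 ms
  resolution into bins `[k, k+1)` ms with integer `k`, and the HRV
  statistic is the Full-Width at Half-Maximum: from the left edge of the
  first bin whose count reaches half the maximum to the right edge of the
  last such bin. Aberrant intervals — ectopic beats, detector errors —
  fall in sparse tail bins below half-maximum and do not widen the
  statistic. No sub-bin interpolation is applied: at 1 ms binning,
  interpolated precision would be spurious. A degenerate series (all
  intervals in one bin) therefore reports 1 ms, the resolution floor.
  Note that intervals measured at a 1000 Hz working rate are integer
  milliseconds; for a Gaussian RR distribution with the generator's
  default 3 ms standard deviation the statistic lands within a bin width
  of the analytic value 2.355 sigma = 7.07 ms.

## Ectopic-beat flagging

An interval is flagged when it deviates from a local moving average by
more than a threshold fraction (default 30%, small enough to trigger on
genuine ectopy and large enough to ignore normal sinus variability). The
reference is the mean of up to 100 intervals *centred on and excluding*
the interval itself (50 before, 50 after). Excluding the interval keeps
an ectopic interval from polluting its own reference; centring treats
pre- and post-event context symmetrically. Where the window meets a
series edge it shrinks symmetrically; at the two endpoints, where no
symmetric window exists, the nearest one-sided neighbours are used so the
reference is defined everywhere. Both window length and threshold are
configuration values.

A premature beat and its compensatory pause both deviate and share a
beat, so runs of consecutive flagged intervals merge into a single region
of interest (ROI), anchored at the first flagged beat and reporting the
run's largest deviation. ROIs are exported as a CSV table plus an
optional multi-page PDF of the band-passed trace ±500 ms around each
flagged beat with detected peaks marked. Classification of the event
(PVC vs PAC vs blocked P vs sinus arrest) is deliberately left to manual
review of the exported windows on the original trace: the package flags
and exports, it does not classify.

## Detector evaluation

Detected and reference annotation sets are matched one-to-one by
nearest-neighbour time difference, greedily by increasing |dt| within a
±10 ms tolerance (about one murine QRS width; configurable). Matched
detections are true positives; unmatched detections false positives;
unmatched references false negatives. True negatives are counted at the
*sample level*: every evaluated sample holding no peak, so
`TP + TN + FP + FN` equals the number of evaluated samples (1,200,000 for
a 20-minute fragment at 1000 Hz). Sensitivity, precision and specificity
follow as `TP/(TP+FN)`, `TP/(TP+FP)` and `TN/(TN+FP)`; a zero denominator
yields `NA`, never zero. Greedy matching can differ from optimal
assignment only in pathological clusters of peaks packed inside one
tolerance window, which the refractory distance rule prevents.

Two detectors evaluated on the same files are compared with a two-sided
paired t-test per metric ("paired samples test" in SPSS terminology); a
Wilcoxon signed-rank option is provided since the parametric choice is a
convention, not a claim about the sampling distribution. Zero-variance
differences return `NA` rather than a fabricated p-value.

The package ships a published benchmark table
(`rpeak_benchmark()`) of per-fragment TP/TN/FP/FN counts for ten
20-minute murine fragments, comparing a custom detector of this design
against the PhysioZoo platform. Recomputing metrics from those counts
reproduces every published six-decimal value; the paired comparison is
run on the published six-decimal metric values themselves, because the
specificity differences are of order 1e-6 and the printed precision is
the meaningful one. Count conservation at exactly 1,200,000 samples holds
for every custom-detector row; the PhysioZoo rows deviate by up to ~0.1%,
a property of the published counts themselves (PhysioZoo evaluated
slightly different sample totals), not of the evaluation convention.

## The synthetic generator

`simulate_ecg()` emulates a resting mouse: RR intervals drawn from a
normal distribution (default mean 100 ms, sd 3 ms) truncated at ±4 sd;
each beat rendered as a sum of Gaussian components for P, Q, R, S and T.
The default morphology — P (0.10 mV, 25 ms before R), Q (-0.35 mV),
R (1.0 mV, sigma 1.15 ms), S (-0.55 mV) at ±3.5 ms, T (0.20 mV, 22 ms
after R) — gives a sharp, deep-S lead II complex about 10-11 ms wide,
as murine lead II typically shows. Leads I and II are rendered with
projection gains (0.55 and 1.0); lead III is the exact Einthoven
difference II - I; noise is then added per lead independently.
Contaminants: sinusoidal baseline wander (default 0.05 mV at 0.4 Hz),
white noise, EMG-band noise placed at 300-600 Hz — above the QRS band,
so band-pass suppression is observable — and Hann-windowed
movement-artifact bursts. Ectopic events are injected at known positions:
a premature beat replaces one interval by `fraction * RR` and the next by
`(2 - fraction) * RR` (the classical fully compensatory pause, conserving
total time); a sinus arrest doubles one interval, optionally rendering a
lone P wave at the skipped beat position (a blocked-P pattern). The
generator returns the exact R-peak sample of every beat and per-beat
ectopic flags, and is bit-reproducible under a fixed seed.

What the generator does *not* emulate: autonomic and circadian HRV
structure, respiratory sinus arrhythmia, electrode-contact drift,
beat-to-beat morphology variation, or the waveform subtleties that
distinguish PVC from PAC. Passing tests on synthetic data therefore
demonstrate the correctness of the algorithms under known ground truth —
not field performance on animal recordings, which depends on trace
quality beyond the generator's scope.

## Numerical and testing choices

* Sample indices are 0-based everywhere (annotations, files, ground
  truth); fragments are half-open intervals, so segmentation conserves
  samples exactly and partial trailing fragments are kept and flagged.
* Amplitudes are mV throughout; readers reject files without a declared
  sample rate rather than guessing.
* The test suite exercises short recordings (20-120 s) for unit-level
  checks and full 20-minute recordings for the end-to-end acceptance
  checks; the Monte-Carlo checks use 10^4 intervals (RR dispersion) and
  10^5 intervals (FWHM against the analytic Gaussian width). Moving
  average and peak matching are verified against brute-force
  recomputations on series up to length 500.
* `scripts/acceptance.R` recomputes the headline quantities from scratch
  at a caller-supplied seed; all synthetic conditions (sample sizes,
  noise levels, event positions) are fixed in the script, not tuned per
  seed.

## Known limitations

* The brick-wall band-pass attaches oscillatory 1/t tails to each QRS;
  the detection-trace units were chosen so the default height threshold
  excludes them, but a user lowering the threshold far below 0.05 mV on
  clean signal will surface them as spurious candidates.
* Plain decimation aliases out-of-band noise into the working band; at
  the default rates this is bounded by the subsequent band-pass, but
  non-integer rate ratios are rejected rather than resampled.
* At working rates below 400 Hz the clipped band-pass retains too little
  QRS energy for reliable detection; the sample-rate sweep
  (`sweep_sample_rates()`) exists precisely to make that degradation
  visible per recording.
* Ectopic flagging is interval-based: events that do not perturb RR
  (e.g. an interpolated PVC with unchanged cycle) are invisible to it.
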