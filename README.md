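# ambecg

Analysis of long-term **ambulatory electrocardiography (AECG) in mice**:
pre-processing, R-peak detection, heart-rate and heart-rate-variability
extraction, ectopic-beat flagging, and quantitative detector evaluation —
plus a synthetic murine ECG generator with exact ground truth so the whole
chain is testable without animal recordings.

Murine ECG defeats human-oriented tooling: heart rates of 500–750 bpm
(RR ≈ 80–120 ms) and a QRS complex only ~10 ms wide put the diagnostic
signal in a frequency band that human pipelines discard. `ambecg`
implements a chain adapted to that signal, exposed as pipe-friendly
functions over tibbles.

## Method at a glance

For each analysed lead (lead II by default, typically the strongest):

1. **zero-phase high-pass** — 2nd-order Butterworth, f_c = 5 Hz, applied
   forward–backward (no phase shift, R-peak positions preserved);
2. **decimation** to a 1000 Hz working rate;
3. **hard FFT band-pass, 100–200 Hz** — isolates the murine QRS band;
4. **zero-phase derivative** — the detection trace.

R peaks are local maxima of the detection trace with height ≥ 0.05 mV
and pairwise separation ≥ 50 ms (greedy by height, earlier peak on ties),
refined onto the band-passed trace. From the detected peaks:

- heart rate `HR = n_peaks / duration` (bpm), mean RR (ms);
- **FWHM HRV** — the width of the 1 ms-binned RR histogram at half its
  maximum count: a variability measure that aberrant intervals in the
  histogram tails cannot inflate;
- **ectopic flags** — intervals deviating > 30% from a 100-interval
  moving average (centred, excluding the interval itself), merged per
  event and exported as review windows (CSV + multi-page PDF).

Detectors are scored against reference annotations by one-to-one
nearest-neighbour matching (±10 ms): `sensitivity = TP/(TP+FN)`,
`precision = TP/(TP+FP)`, `specificity = TN/(TN+FP)`, with TN counted at
the sample level. Two detectors are compared with a paired t-test per
metric.

## Worked example

Simulate two minutes of murine ECG (600 bpm, one premature beat injected
at t = 60 s), run the chain, and check the detector against the known
truth:

```r
library(ambecg)

cfg <- sim_config(duration_s = 120, seed = 42,
                  ectopic = list(ectopic_event("premature", at_s = 60,
                                               fraction = 0.6)))
sim  <- simulate_ecg(cfg)
pre  <- preprocess_ecg(sim$record)          # 2000 Hz -> 1000 Hz working rate
beats <- detect_r_peaks(pre$detection, pre$bandpassed, 1000)

beat_summary(beats, 120)
#>   n_peaks hr_bpm mean_rr_ms rr_sd_ms fwhm_ms
#> 1    1201   600.       99.9     3.48       7
```

1201 beats in 120 s is 600.5 bpm; the FWHM of 7 ms matches the analytic
width of the simulated Gaussian RR distribution (2.355 × 3 ms ≈ 7 ms).
The injected premature beat is flagged — and nothing else is:

```r
flag_ectopic(rr_intervals(beats))
#>   beat_index time_s interval_ms moving_avg_ms deviation_fraction
#> 1        601 59.964         145         99.41          0.4586058
```

(The premature interval and its compensatory pause merge into one region
of interest; the 145 ms pause deviates 46% from the local 99.4 ms moving
average.) Against the simulator's ground truth the detector is perfect:

```r
ref <- beat_annotations(sim$truth$sample, 2000, source = "reference")
match_peaks(beats, ref, tolerance_ms = 10, total_samples = 120 * 1000)
#>     tp     tn fp fn sensitivity precision specificity
#> 1 1201 118799  0  0           1         1           1
```

The package also ships a published murine benchmark
(`rpeak_benchmark()`): per-fragment detection counts for ten 20-minute
fragments, custom detector vs the PhysioZoo platform. Evaluating it
reproduces the published metrics and the paired comparison:

```r
glance(evaluate_counts(rpeak_benchmark()[, c("method","file","tp","tn","fp","fn")]))
#>   sensitivity precision specificity p_sensitivity p_precision p_specificity
#> 1   0.9985658 0.9985829   0.9999851     0.1437137    0.408172     0.3981535
```

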