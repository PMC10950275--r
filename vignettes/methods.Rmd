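---
title: "Detection and velocity estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and velocity estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantephys)
```

## The analysis problem

Extracellular plant recordings are acquired with an AC-coupled amplifier
(single-channel rig: gain 72x, 0.07-8.8 Hz band; two-channel rig: gain
~55x, 0.2-130 Hz) at 10 kHz, stored as WAV files, and annotated by hand
with stimulus markers ("1" stimulus applied, "2" removed). The signals of
interest are seconds-scale wound potentials following a flame stimulus,
with onset latencies of roughly 3-6 s, and faster action potentials in
touch-sensitive species. Because the AC coupling destroys absolute DC
levels, all amplitudes are arbitrary units on the ADC's normalized
+/-1 full scale, and analyses work with ranges, ratios and normalized
epochs rather than millivolts.

The pipeline has four analysis stages, each of which can be driven from R
or from the thin command-line front end in `inst/cli/plantephys.R`:

1. **Artifact rejection** (`reject_trace`): discard whole traces with
   movement/touch spikes faster than 500 ms, amplifier clipping, or
   spikes riding on an elevated baseline.
2. **Response detection** (`classify_response`): a trial is responsive
   when the post-stimulus signal deviates more than 75% outside the
   pre-stimulus signal range.
3. **Species libraries** (`build_species_library`): normalized,
   peak-aligned epochs averaged per species when at least 10 peaks
   survive rejection.
4. **Conduction velocity** (`peak_lag`, `estimate_velocity`): electrode
   separation divided by the inter-channel peak lag on two-channel
   recordings.

A seeded synthetic generator (`generate_recording`,
`generate_two_channel`, `generate_cohort`) reproduces the statistical
structure the stages assume, so every stage is testable without the raw
recordings.

## The detection criterion

Let `[lo, hi]` be the signal's min/max over the 30 s before the stimulus
marker and `R = hi - lo`. A trial is *responsive* iff some sample in the
60 s after the stimulus lies strictly above `hi + 0.75 R` or strictly
below `lo - 0.75 R`. The criterion is two-sided and scale-free, so it is
invariant to constant offsets and to sign flips; "more than" is
implemented strictly, so an excursion exactly at the threshold does not
count. The criterion is evaluated on the baseline-subtracted raw trace,
before normalization: normalizing first would divide both the range and
the excursion by the same constant and change nothing, but running on raw
traces keeps the reported ranges interpretable.

Two defaults matter here. The pre-stimulus window (30 s) and response
window (60 s) bracket the seconds-scale responses; both are
configurable in `detection_config()`. A degenerate, essentially flat
pre-stimulus baseline is widened to a small floor
(`min_prestim_range`, four 16-bit quantization steps) so that a
perfectly quiet recording cannot be declared responsive on quantization
noise.

**Onset latency.** The first criterion crossing *proves* a response, but
its time overestimates the onset: the signal must first climb through
the entire 75% excursion, which takes up to ~0.7 s at unlucky noise and
drift phases. The onset estimator therefore backtracks from the first
crossing to the last sample still inside `[lo, hi]` — the point where the
trace departed the pre-stimulus range on its way to the crossing. The
test suite bounds the mean absolute latency error at 0.5 s over 100
seeded wound-potential fixtures; the backtracked estimator sits far
inside that bound.

## Preprocessing conventions

Epochs destined for species averages are processed in a fixed order:
baseline subtraction (median of the pre-stimulus window; the median is
robust to pre-stimulus artifacts), sign inversion when the extremum is a
negative minimum (ties `|min| == |max|` are left unchanged), amplitude
normalization (extremum exactly 1), and peak alignment into a common
`[-10, +60]` s window with zero-padding (flagged) where a window leaves
the recording. The composition leaves every epoch with value +1 exactly
at the anchor index, which is what pointwise means and SDs assume.
Whether alignment should use the global extremum or the first
suprathreshold peak is genuinely open; the global extremum is used
because it is parameter-free and stable under noise.

## Artifact filters

All three filters work from one decomposition: the trace (decimated to
100 Hz; see below) minus its *trailing* 30 s rolling-median baseline.
Excursions where this residual exceeds a threshold are candidate spikes;
a spike's width is measured at half its prominence.

- **fast_spike**: any excursion narrower than 500 ms. Genuine plant
  responses are seconds wide; sub-500 ms transients are wire touches.
- **clipping**: any run of at least 50 ms within 1% of the +/-1 full
  scale, checked at the native rate. The true hardware clip level is
  unrecoverable from a WAV, so saturation of the normalized scale is the
  operative definition.
- **elevated_baseline**: a detected spike near which the rolling-median
  baseline magnitude exceeds 75% of the trace's global extremum. Such a
  trace cannot be meaningfully normalized. This is the most
  interpretation-dependent of the three rules (the reference level for
  "75%" is not uniquely determined by its verbal description); the
  implemented reading is recorded here rather than asserted as the only
  possible one.

Numerical choices, and why:

- **Threshold = 10 raw MADs of the residual, floored at 0.05 full
  scale.** The MAD is estimated on the pre-stimulus segment so genuine
  responses cannot inflate it. Ten raw (unscaled) MADs is about 6.7
  Gaussian SDs: by the Rice upcrossing rate, a 120 s band-limited trace
  crosses that level by chance with expectation far below one, so clean
  traces essentially never fire; at 5 raw MADs (3.4 SDs) a clean trace
  would average several false excursions. The absolute floor keeps
  quiet, response-free traces — where the MAD can be a few thousandths
  of full scale — from flagging drift-scale wiggles; real touch
  artifacts are an order of magnitude above it.
- **Trailing, not centered, median.** A centered rolling median follows
  a persistent baseline step with no lag at all (the step fills half the
  window immediately), so steps would never leave a residual. The
  trailing median lags by half a window and converts a step into a wide
  excursion over an elevated baseline — exactly the normalization
  artifact the third filter targets.
- **30 s baseline window.** Much longer than any genuine response (so
  wound potentials are not mistaken for baseline shifts) and much
  shorter than the record.
- **100 Hz analysis rate.** Spike detection runs on a stride-decimated
  copy: the single-channel amplifier band ends at 8.8 Hz, so
  subsampling to 100 Hz is alias-free by construction; on the wider
  two-channel band, aliased broadband noise only enters the (floored)
  threshold estimate, never a spike's shape. 10 ms resolution is well
  under the 50 ms narrowest artifact of interest.

## Conduction velocity

Velocity is electrode separation divided by the time difference between
the response peaks on the two channels, `v = d / |Δt|`, with the sign of
the lag giving the propagation direction. Peaks are located on the
baseline-subtracted response windows after a gentle zero-phase 2 Hz
low-pass; the smoother is identical on both channels, so it cannot bias
the lag, but it prevents broadband noise from displacing the peak
sample. A windowed cross-correlation estimator is provided as a
robustness alternative (`method = "cross_correlation"`); on clean
fixtures the two agree to within a couple of sample periods.

Every estimate carries a quantization bound — the velocity change
implied by one sample period of lag error,
`d (1/|Δt| - 1/(|Δt| + T))` — which at 10 kHz and multi-second lags is
of order 10^-4 mm/s; peak-time jitter from noise, not quantization, is
the practical error floor. Separations are user-supplied per recording
(they were measured by hand at acquisition); the study helper
`preset_velocity_study()` uses 15 mm, the midpoint of the 1-2 cm
electrode spacing.

## What the synthetic generator emulates

Each synthetic recording is 120 s at 10 kHz with the stimulus at 30 s
(the "off" marker 3 s later, the midpoint of the 2-4 s stimulus hold).
A responsive preset embeds a double-exponential deflection — rise time
constant 1 s and decay 8 s for wound potentials; rise `duration/6`,
decay `duration/3` for action potentials of 2 s (fast) or 10 s (slow)
duration — at a latency drawn uniformly from 3-6 s, with polarity
negative in half of the recordings to exercise the sign-inversion rule.
The pre-amplifier signal adds three nuisances: white electrode noise
(SD one tenth of the response amplitude, i.e. SNR 10, expressed as a
density so it is sampling-rate independent), sinusoidal drift of period
300 s (electrode polarization and temperature act on multi-minute
scales; the AC coupling suppresses this ~20-fold, leaving a visible but
subdominant wander), and mains hum at 50 Hz. Two-channel presets delay
channel 2's waveform by `d / v_true` with independent noise per channel
and hum set low (0.02 a.u.): the 0.2-130 Hz band passes 50 Hz, and the
acquisition deliberately ran on battery power to suppress hum. The
two-channel preset velocity tables are the fixed series
2.2, 2.4, ..., 4.2 mm/s (11 recordings, mean exactly 3.2 mm/s) for the
sundew study, and single velocities 9 mm/s (tomato, flame) and 8 mm/s
(mimosa, tactile).

**The amplifier model is causal.** The band limits are applied as a
causal one-pole RC high-pass at the lower corner followed by a
zero-phase FFT low-pass whose raised-cosine transition ends exactly at
the upper corner (so the stopband above it is empty). An idealized
zero-phase high-pass was rejected: it smears an acausal trough *ahead*
of every slow deflection, contaminating the pre-stimulus window the
detection criterion is anchored to and biasing recovered latencies
early by whole seconds. The causal filter behaves like the real front
end — slow deflections
droop and undershoot after their onset, never before. One consequence
is spectral: an AC-coupled causal filter attenuates but does not
annihilate sub-corner content, so a quiet trace's largest single
spectral line is residual drift below 0.07 Hz, exactly as in the real
instrument. The band-confinement property is therefore verified on the
amplifier model's canonical input (broadband white noise: less than 1%
of output power falls outside the band, measured with a Hann-tapered
periodogram, and exactly none above the upper corner) rather than on
full recordings. The FFT filtering reflect-pads the signal first;
without that, components that are not periodic in the record length
(hum especially) ring audible "clicks" into the first and last second
of every trace.

Artifact injection (`inject_artifact`) adds a Gaussian transient of
half-width 50-300 ms at 10x the trace SD (fast spike), saturates
200-500 ms at full scale (clipping), or adds a sustained step of 160%
of the trace's peak (capped below clip level) from a random time in the
second half of the record (baseline jump).

What the generator does **not** emulate: biophysics (waveforms are
phenomenological, not cable-equation solutions), amplitude variation
across species (amplitudes are configuration, not inference),
non-stationary noise, wind and watering disturbances, or electrode
degradation over a session. Passing tests on synthetic data therefore
demonstrate that the *algorithms* implement their definitions and
recover known ground truth under the stated noise model — not that the
thresholds are optimal for any particular greenhouse.

## Problem sizes used in the checks

The test suite exercises the study-scale conditions directly: a
16-species cohort (9 responsive, 7 noise-only) analysed end to end; 100
wound-potential fixtures for latency recovery (mean absolute error
bound 0.5 s) and 100 noise-only fixtures for the false-positive rate
(bound 5%); 50 clean fixtures plus one injection of each artifact kind
per fixture (detection bound 95% per kind, zero false rejections); and
velocity recovery across the preset tables (sundew mean within 5%,
tomato and mimosa within 10%). Unit tests run the same operations at
reduced sampling rates, which the rate-agnostic containers make
equivalent up to noise density.

## Known limitations

- The "elevated baseline of 75%" rule is one defensible formalization
  of an ambiguous verbal description; reports flag the reason so
  downstream users can audit it.
- The "at least 10 peaks" library rule is read as >= 10 pooled
  peak-aligned epochs per species; a per-recording reading is possible
  and not implemented.
- Event markers are keyed by hand at acquisition; the parser accepts
  fractional seconds but the true marker precision is unknown, so
  sub-second latency differences between recordings inherit that
  uncertainty.
- Velocity direction is reported, but with two electrodes the geometry
  cannot distinguish propagation paths; multi-electrode mapping is out
  of scope.
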