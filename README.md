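# PulseAttractor

Attractor reconstruction of arterial pulse waveforms: a quantitative,
baseline-wander-insensitive representation of waveform morphology for
physiologists, clinical researchers and biosignal engineers who work with
long records of approximately periodic signals (invasive arterial blood
pressure, PPG/finger-cuff pressure, and similar).

Conventional monitors reduce thousands of high-fidelity samples to a
handful of averaged numbers (heart rate, systolic/diastolic pressure) and
discard the waveform shape. This package instead embeds the raw signal in
three dimensions with delay coordinates (Takens),

    (x(t), x(t − τ), x(t − 2τ)),        τ = T/3,

where `T` is the average cycle length, and rotates the trajectory with the
orthonormal basis

    u = (x + y + z)/√3,   v = (x + y − 2z)/√6,   w = (x − y)/√2,

so that `u` (the cube's main diagonal) carries the absolute level, while
the `(v, w)` plane — the view "down one corner" of the cube — carries pure
morphology. An approximately periodic signal traces a triangular attractor
in `(v, w)` whose geometry maps onto physiology:

| Attractor feature | Waveform / physiological correlate |
|---|---|
| cycle length `T`, HR = 60/T | heart rate, from the whole waveform (no peak detection) |
| size `S` (0.95-quantile radius, calibrated) | pulse pressure (∝ amplitude) |
| rotation θ ∈ (−60°, 60°] | downstroke concavity (clockwise = more concave) |
| arm widths (RMS spread of the three sides) | beat-to-beat variability of specific waveform segments |
| edge-density CV | non-uniform dwell along a side (upstroke convexity) |
| periodicity = mean width / S | overall waveform repeatability (0 = perfectly periodic) |
| `u` mean / trend | absolute level and its drift |

Cycle length is estimated by a normalized autocorrelation-like statistic
(fixed-overlap lagged correlation with a fundamental-vs-harmonic guard),
and a three-cycle running mean is removed before the morphology embedding
so that slow baseline wander — which leaks into `(v, w)` at first order in
`ωτ` — cannot masquerade as a morphology change. Features are tracked over
sliding windows, re-estimating `T` per window for non-stationary records.

The package also includes a parametric in-silico pulse generator
(half-cosine upstroke, power-law downstroke with concavity exponent κ,
per-beat period/amplitude/upstroke-fraction jitter, wander, drift, noise)
with retrievable per-beat ground truth, used throughout the test suite.

## Worked example

```r
library(PulseAttractor)

params <- pulseParams(period = 0.8, amplitude = 40, offset = 80,
                      sdPeriod = 0.01, sdAmplitude = 0.03, seed = 42L)
sig <- generatePulseTrain(params, durationS = 60, fs = 250)
sig
#> PulseSignal: 15000 samples @ 250 Hz (60.000 s), t0 = 0 s, units = arbitrary
#>   with per-beat ground truth (75 beats)

res <- track(sig, windowSpec(10, 5))
head(res[, c("window_start_s", "T_s", "HR_bpm", "size", "rotation_deg",
             "periodicity", "u_mean")], 3)
#>   window_start_s    T_s  HR_bpm    size rotation_deg periodicity  u_mean
#> 1              0 0.8044 74.5881 44.9966      -6.9340      0.0125 96.8981
#> 2              5 0.8033 74.6954 44.9883      -6.9725      0.0142 96.7954
#> 3             10 0.7950 75.4684 45.4078      -6.9915      0.0162 96.7951
```

Reading the first row: the estimated cycle length 0.804 s (≈ 74.6 bpm)
matches the generator's nominal 0.8 s beat; the attractor size ≈ 45 units
tracks the 40-unit pulse amplitude (the default concavity κ = 1.5 makes
the attractor slightly larger than the straight-downstroke calibration
shape); the rotation of −6.9° reflects that concave downstroke (clockwise
= negative); the periodicity score ≈ 0.013 says the arms are thin — the
small period/amplitude jitter leaves an almost-periodic waveform; and
`u_mean` ≈ 96.9 is the absolute window mean (diastolic offset 80 plus the
time-average of the pulse), which lives only in the `u` coordinate.

A command-line interface with `synth`, `track`, `attractor` and
`features` subcommands is installed at `inst/scripts/pulseattractor`:

```sh
Rscript inst/scripts/pulseattractor synth --out s.csv --duration 60 --fs 250 --period 0.8
Rscript inst/scripts/pulseattractor track --input s.csv --out f.csv --window 10 --step 5
```

## Acceptance script

`scripts/acceptance.R` regenerates the package's reference quantity from
scratch: it synthesizes a noise-free pulse train with an 89 ms beat
period sampled at 1000 Hz for 2 s, runs the cycle-length estimator over
the mouse search range, converts to heart rate, and writes the result as
JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
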