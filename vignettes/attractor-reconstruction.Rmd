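---
title: "Attractor reconstruction of pulse waveforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor reconstruction of pulse waveforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PulseAttractor)
```

## The model

An approximately periodic scalar signal $x(t)$ — an arterial pressure or
PPG waveform — is embedded in three dimensions with delay coordinates,

$$\mathbf{p}(t) = \big(x(t),\; x(t-\tau),\; x(t-2\tau)\big),$$

with the delay set to one third of the average cycle length,
$\tau = T/3$. For an exactly $T$-periodic signal the trajectory is a
closed loop; advancing time by $T/3$ cyclically permutes the three
coordinates, which is why this choice of $\tau$ produces a point set with
three-fold rotational symmetry — the triangular attractor — in the plane
orthogonal to the $(1,1,1)$ diagonal. The orthonormal change of basis

$$u = \tfrac{x+y+z}{\sqrt3},\qquad
  v = \tfrac{x+y-2z}{\sqrt6},\qquad
  w = \tfrac{x-y}{\sqrt2}$$

splits every point into a baseline coordinate $u$ (all three delayed
copies move together when the level shifts: adding a constant $c$ to the
signal moves $u$ by $c\sqrt3$ and leaves $(v,w)$ exactly unchanged) and a
morphology plane $(v,w)$. Norms are preserved, so amplitudes keep their
physical units in either representation.

All quantification happens on the $(v,w)$ point cloud of a window:

* **Cycle length / heart rate.** $T$ is the smallest strongly supported
  local maximum of a lagged-correlation curve (below); $\mathrm{HR} =
  60/T$ bpm.
* **Size.** $S = c_0\, q_{0.95}(r)$, the 0.95 quantile of point radii
  scaled by a fixed calibration constant. $S$ is exactly homogeneous
  ($S(kx) = kS(x)$) and proportional to pulse pressure.
* **Rotation.** $\theta = \tfrac13 \arg \sum_{\text{cells}} \rho\,
  e^{3i\varphi}$ on the density grid, referenced to the calibration
  waveform and wrapped to $(-60^\circ, 60^\circ]$. The order-3 moment is
  the lowest angular harmonic a three-fold-symmetric shape supports, and
  it is exactly equivariant under rotations of the cloud. A more concave
  downstroke rotates the attractor clockwise, i.e. $\theta$ decreases.
* **Arm widths and edge uniformity.** After de-rotating by $-\theta$ the
  cloud is partitioned into three $120^\circ$ sectors centred on the
  canonical side directions; each sector's points are fitted by
  total-least-squares and the width is the RMS perpendicular residual.
  The coefficient of variation of point counts in 20 bins along the
  fitted side (5th–95th percentile span) measures non-uniform dwell.
* **Periodicity.** Mean arm width over $S$; 0 for a perfectly repeating
  waveform, growing as beat-to-beat variability diffuses the attractor.
* **$u$ statistics.** $\bar u/\sqrt3$ equals the window mean of the raw
  signal; its least-squares slope tracks slow pressure trends. These are
  deliberately the only features that see the absolute level.

## Cycle-length estimation

The estimator is a normalized autocorrelation variant: the mean-removed
window head $x_{1..M}$ (with $M$ = window length minus the largest lag)
is correlated against its lag-$k$ shift for every lag in the search
range, using the *same* overlap length $M$ for every $k$. The fixed
overlap matters: the classical biased estimator multiplies the
correlation by a factor that decays with lag, which tilts the peak
toward smaller lags. On a noise-free 89 ms pulse train sampled at
1000 Hz that tilt is enough to move the rounded heart rate from 674 to
675 bpm; the fixed-overlap Pearson form recovers the peak at 89.000 ms.
Candidate periods are local maxima only; to avoid locking onto a
harmonic or subharmonic, the smallest candidate scoring at least 0.8 of
the best in-range score is chosen (the guard is configurable), then
refined to sub-sample precision by a quadratic fit through the peak and
its neighbours.

Default search ranges are species presets: 30–300 bpm (`"human"`),
300–800 bpm (`"mouse"`). The window must cover at least three times the
largest candidate period.

## Baseline wander and the residual-trend correction

The projection discards *constant* offsets exactly, but a wander
$W(t) = A_w \sin(2\pi f t)$ enters $(v,w)$ through the differences
$W(t) - W(t-\tau)$, of first order $\sim 3 A_w \omega\tau/\sqrt6$. At
$f = 0.05/T$ and $\tau = T/3$ that is $\approx 0.13\,A_w$ — a double-digit
percentage of the attractor radius when the wander amplitude rivals the
pulse amplitude. The pipeline therefore subtracts a centred running mean
spanning **three** estimated cycles from the signal before the
morphology embedding (edges without a full window are trimmed). For a
periodic signal whose period divides the span, the running mean is
exactly constant, so the attractor is untouched; a slow wander passes
into the trend almost unattenuated (boxcar response
$\mathrm{sinc}(3 f T) \approx 0.96$ at $f = 0.05/T$) and is removed,
leaving a measured size error of about 0.5%. Three cycles is a
compromise: a one-cycle mean removes wander even better but converts
per-beat jitter into a trend wiggle that smears all three arms; much
longer spans let wander back through. The $u$ statistics use the raw,
uncorrected embedding, since their whole purpose is to report the level
and its drift. No other preprocessing (filtering, detrending of the
stored signal) is performed anywhere; artifact removal is the user's
only editing tool.

## Calibration constants

"Size" and "rotation zero" need a reference. Both are fixed once against
an ideal calibration waveform: period 1 s, amplitude 1, upstroke
fraction 0.2, straight downstroke ($\kappa = 1$), 500 Hz, 20 s, no
stochastic terms. $c_0$ is the reciprocal of that waveform's 0.95
radius quantile ($c_0 \approx 1.697$), so the calibration waveform with
amplitude $A$ measures $S = A$ exactly, and any amplitude-scaled copy
follows by homogeneity. The calibration attractor's raw order-3 angle
($\approx -30^\circ$) becomes the rotation reference, and its corner
directions define the canonical side sectors (centres at $30^\circ$,
$150^\circ$, $-90^\circ$); arm 1 is the sector containing the positive
$v$ axis. The constants are recomputed deterministically per session and
cached — there are no frozen magic numbers to go stale.

Note that size equals pulse amplitude only for the calibration shape;
other morphologies are proportional with a nearby constant (the default
$\kappa = 1.5$ generator reads about 12% high). This mirrors the fact
that only *relative* size tracks pulse-pressure change.

## The in-silico generator

The generator is the package's stated experimental world. One beat of
realized period $T_i$ rises from the offset to offset $+ A_i$ over
$\alpha_i T_i$ as a half-cosine and decays as
$A_i (1-s)^{\kappa}$, where the downstroke phase is normalized by the
*nominal* upstroke fraction, $s = (p - \alpha_i)/(1 - \alpha)$.
The nominal normalization is deliberate: it keeps the downstroke
template (shape and slope) identical across beats when only the
upstroke fraction jitters — the classic manipulation "alter the
upstroke gradient while total period and downstroke stay fixed". The
price is a small foot-level step of $A_i(\alpha_i -
\alpha)/(1-\alpha)$ per beat (clipped at baseline when early), which is
also the mechanism that makes upstroke jitter observable: embedding
triples that straddle a beat boundary with their *middle* coordinate on
an upstroke are displaced perpendicular to exactly one arm, whereas
triples whose lagged pair lies within a single beat slide *along* their
arm. This is why upstroke-gradient variability widens one specific arm
(arm 1 under this package's conventions — the empirical "upstroke
arm"), while the other two arms retain only a monotone but tiny creep
(&le; 0.25% of size at the largest jitter tested, versus 1.5% for arm 1)
from corner points shared between sectors. The widened/thin distinction
uses the periodic-waveform bound: an arm has "widened" when its RMS
width exceeds 1% of the attractor size.

Other defaults state plausible physiology and are not revisited: period
1 s (60 bpm) and amplitude 40 with offset 80 (a 120/80-style pressure in
mmHg-like units) for human-scale examples; upstroke fraction 0.2 of the
beat; concavity 1.5 (mildly concave arterial runoff; 1 is reserved for
the calibration shape); all jitters, wander, drift and noise default to
zero so every stochastic term is opt-in and explicit. Jitters are i.i.d.
Gaussian clamped at $\pm 4$ sd (one draw per beat, so the random stream
is independent of the clamping), and realized upstroke fractions are
kept inside $(0.005, 0.995)$. Per-beat ground truth is stored in the
signal's metadata for oracle comparisons. The generator does **not**
model dicrotic notches, reflected waves, or any forward hemodynamic
model (Windkessel etc.); a green test on this world establishes the
estimator's geometry and invariances, not clinical validity on real
arterial data, which additionally shows notches, non-Gaussian artifact
bursts and correlated beat-to-beat dynamics.

## Numerical choices, degenerate inputs, limitations

* Delayed coordinates use linear interpolation — exact on locally linear
  segments, error bounded by curvature $\times (1/f_s)^2$; delays that
  are integer multiples of the sample step reduce to index shifts.
* The density grid defaults to $128^2$ with a per-window extent of 1.05
  times the largest radius; fixed-extent mode makes densities comparable
  across windows and drops (then renormalizes) out-of-range points.
  Points exactly on the upper edge belong to the last bin.
* Symmetrization rotates the grid by 120° and 240° with bilinear
  resampling; it is idempotent and mass-preserving only up to resampling
  tolerance, which is why size works on point radii (exact under the
  symmetrization, since rotation preserves radii) rather than on the
  grid.
* A density whose order-3 moment magnitude is below $10^{-6}$ has no
  triangular orientation and `rotationAngle()` refuses to answer rather
  than return noise; windows in `track()` that fail any stage are
  emitted with the failure message in their `flag`, never dropped.
* A constant (zero-variance) window has no periodicity and errors; a
  degenerate single-point cloud has size 0; sectors with fewer than 30
  points report `NA` widths.
* Sub-sample peak refinement clamps the quadratic-interpolation offset
  to half a sample, so a pathological plateau cannot throw the estimate
  outside the bracketing lags.
* Windows are placed only where they fit entirely inside an unmasked
  segment; a window straddling an artifact is skipped by construction
  (segments are windowed independently). This is the only
  mask/window-boundary policy the package implements.
* Heart-rate independence holds by construction ($\tau$ scales with the
  estimated $T$), verified to within 2% under exact time rescaling; the
  residual comes from resampling interpolation, not the method.
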