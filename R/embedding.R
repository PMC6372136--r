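## Delay-coordinate embedding and the u/(v,w) split.

#' Build the 3D delay-coordinate trajectory
#'
#' For each sample time `t_k >= t0 + 2 tau` emits the triple
#' `(x(t_k), x(t_k - tau), x(t_k - 2 tau))`. Delayed values falling
#' between samples are linearly interpolated, which is exact on locally
#' linear segments; when `tau` is an exact multiple of `1/fs` the lagged
#' coordinates are pure index shifts.
#'
#' @param signal a [PulseSignal-class] with duration `> 2 * tau`.
#' @param tau delay in seconds, typically one third of the average cycle
#'   length.
#' @return a [Trajectory3-class].
#' @export
delayEmbed <- function(signal, tau) {
  stopifnot(is(signal, "PulseSignal"))
  if (tau <= 0) stop("tau must be positive")
  if (duration(signal) <= 2 * tau)
    stop("tau too large: signal duration must exceed 2 * tau")
  fs <- sampleRate(signal)
  x <- samples(signal)
  t <- (seq_along(x) - 1) / fs
  k0 <- which(t >= 2 * tau - 1e-12)[1L]
  tk <- t[k0:length(x)]
  xi <- x[k0:length(x)]
  yi <- stats::approx(t, x, tk - tau)$y
  zi <- stats::approx(t, x, tk - 2 * tau)$y
  new("Trajectory3", x = xi, y = yi, z = zi, tau = tau, fs = fs,
      t0 = startTime(signal) + tk[1L])
}

#' Rotate a trajectory into baseline/morphology coordinates
#'
#' Applies the orthonormal basis
#' `u = (x + y + z)/sqrt(3)`, `v = (x + y - 2 z)/sqrt(6)`,
#' `w = (x - y)/sqrt(2)`, so `u` lies along the `(1,1,1)` diagonal
#' (carrying the baseline level) and `(v, w)` span the orthogonal plane
#' (carrying the waveform morphology). Norms are preserved:
#' `u^2 + v^2 + w^2 = x^2 + y^2 + z^2`. Adding a constant to the signal
#' leaves `(v, w)` exactly unchanged and shifts `u` by `c * sqrt(3)`.
#'
#' @param traj a [Trajectory3-class].
#' @return a [UVWSeries-class].
#' @export
projectUVW <- function(traj) {
  stopifnot(is(traj, "Trajectory3"))
  new("UVWSeries",
      u = (traj@x + traj@y + traj@z) / sqrt(3),
      v = (traj@x + traj@y - 2 * traj@z) / sqrt(6),
      w = (traj@x - traj@y) / sqrt(2),
      tau = traj@tau, fs = traj@fs, t0 = traj@t0)
}

#' Remove the slow baseline trend from a signal
#'
#' Subtracts a centred running mean spanning `cycles` pulse periods and
#' trims the edges where the full averaging window is unavailable. For an
#' exactly periodic signal whose period divides the averaging span the
#' trend is exactly constant, so the morphology is untouched; slow
#' baseline wander (frequencies at or below about `0.05 / period`) passes
#' into the trend almost unattenuated and is removed. This is used by the
#' feature pipeline before the morphology (v, w) embedding; the projection
#' itself discards only strictly constant offsets, and the residual of a
#' slow wander would otherwise leak into the attractor plane in
#' proportion to the wander frequency times the delay.
#'
#' @param signal a [PulseSignal-class].
#' @param period pulse period in seconds (typically the cycle-length
#'   estimate of the window).
#' @param cycles width of the averaging window in periods; default 3
#'   (shorter windows track beat-to-beat jitter into the trend, longer
#'   ones let more wander through).
#' @return a trimmed, baseline-corrected [PulseSignal-class]; its
#'   `metadata$trend` holds the subtracted trend.
#' @export
removeBaseline <- function(signal, period, cycles = 3) {
  stopifnot(is(signal, "PulseSignal"))
  if (period <= 0) stop("period must be positive")
  fs <- sampleRate(signal)
  L <- max(2L, as.integer(round(cycles * period * fs)))
  x <- samples(signal)
  N <- length(x)
  if (L >= N) stop("signal too short for the baseline window (",
                   L, " samples)")
  h1 <- (L - 1L) %/% 2L
  h2 <- L - 1L - h1
  cs <- cumsum(c(0, x))
  idx <- (h1 + 1L):(N - h2)
  trend <- (cs[idx + h2 + 1L] - cs[idx - h1]) / L
  pulseSignal(x[idx] - trend, fs = fs,
              t0 = startTime(signal) + h1 / fs,
              units = signalUnits(signal),
              metadata = list(trend = trend))
}
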