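## Core S4 containers for waveform data, embeddings and attractor features.

#' PulseSignal: a uniformly sampled single-channel waveform
#'
#' Container for a uniformly sampled scalar time series (arterial blood
#' pressure, PPG, or any approximately periodic signal). Sample `i`
#' (1-based) covers the half-open time interval
#' `[t0 + (i-1)/fs, t0 + i/fs)`.
#'
#' @slot samples numeric vector of sample values (finite).
#' @slot fs sampling rate in Hz, `> 0`.
#' @slot t0 start time of the first sample in seconds.
#' @slot units free-text unit label (e.g. `"mmHg"`).
#' @slot metadata list of optional annotations; the in-silico generator
#'   stores per-beat ground truth under `$beats` and the generating
#'   parameters under `$params`.
#'
#' @examples
#' s <- pulseSignal(sin(2 * pi * (0:999) / 100), fs = 100)
#' duration(s)
#' @aliases samples sampleRate startTime signalUnits nSamples duration
#'   sampleTimes beatTruth
#' @export
setClass("PulseSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 units = "character", metadata = "list"))

setValidity("PulseSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "signal must contain at least one sample")
  if (anyNA(object@samples) || !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @param units unit label.
#' @param metadata list of annotations.
#' @rdname PulseSignal-class
#' @export
pulseSignal <- function(samples, fs, t0 = 0, units = "arbitrary",
                        metadata = list()) {
  new("PulseSignal", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0), units = as.character(units), metadata = metadata)
}

#' @rdname PulseSignal-class
#' @export
setMethod("samples", "PulseSignal", function(object) object@samples)

#' @rdname PulseSignal-class
#' @export
setMethod("sampleRate", "PulseSignal", function(object) object@fs)

#' @rdname PulseSignal-class
#' @export
setMethod("startTime", "PulseSignal", function(object) object@t0)

#' @rdname PulseSignal-class
#' @export
setMethod("signalUnits", "PulseSignal", function(object) object@units)

#' @rdname PulseSignal-class
#' @export
setMethod("nSamples", "PulseSignal", function(object) length(object@samples))

#' @rdname PulseSignal-class
#' @export
setMethod("duration", "PulseSignal",
          function(object) length(object@samples) / object@fs)

#' @rdname PulseSignal-class
#' @export
setMethod("sampleTimes", "PulseSignal", function(object)
  object@t0 + (seq_along(object@samples) - 1) / object@fs)

#' @rdname PulseSignal-class
#' @export
setMethod("beatTruth", "PulseSignal", function(object) object@metadata$beats)

setMethod("show", "PulseSignal", function(object) {
  cat(sprintf("PulseSignal: %d samples @ %g Hz (%.3f s), t0 = %g s, units = %s\n",
              nSamples(object), sampleRate(object), duration(object),
              startTime(object), signalUnits(object)))
  if (!is.null(object@metadata$beats))
    cat(sprintf("  with per-beat ground truth (%d beats)\n",
                nrow(object@metadata$beats)))
})

#' ArtifactMask: time intervals to exclude from analysis
#'
#' Half-open intervals `[start, end)` in seconds marking non-physiological
#' artifacts. Intervals are normalized on construction: sorted, merged when
#' overlapping or touching.
#'
#' @slot intervals two-column numeric matrix (`start`, `end`) in seconds.
#' @aliases maskIntervals
#' @export
setClass("ArtifactMask", representation(intervals = "matrix"))

setValidity("ArtifactMask", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns")
  if (nrow(iv)) {
    if (any(!is.finite(iv))) return("interval bounds must be finite")
    if (any(iv[, 1] >= iv[, 2])) return("each interval needs start < end")
    if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2]))
      return("intervals must be non-overlapping and sorted")
  }
  TRUE
})

#' @param start,end numeric vectors of interval bounds in seconds, or
#'   `start` may be a two-column matrix.
#' @rdname ArtifactMask-class
#' @export
artifactMask <- function(start = numeric(), end = numeric()) {
  if (is.matrix(start)) {
    end <- start[, 2]
    start <- start[, 1]
  }
  stopifnot(length(start) == length(end))
  if (length(start)) {
    if (any(start >= end)) stop("each mask interval needs start < end")
    o <- order(start)
    start <- start[o]; end <- end[o]
    ## merge overlapping/touching intervals
    ms <- start[1]; me <- end[1]; os <- numeric(); oe <- numeric()
    for (i in seq_along(start)[-1]) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        os <- c(os, ms); oe <- c(oe, me)
        ms <- start[i]; me <- end[i]
      }
    }
    start <- c(os, ms); end <- c(oe, me)
  }
  new("ArtifactMask", intervals = cbind(start = start, end = end))
}

#' @rdname ArtifactMask-class
#' @export
setMethod("maskIntervals", "ArtifactMask", function(object) object@intervals)

setMethod("show", "ArtifactMask", function(object) {
  cat(sprintf("ArtifactMask: %d interval(s), %.3f s masked in total\n",
              nrow(object@intervals),
              sum(object@intervals[, 2] - object@intervals[, 1])))
})

#' WindowSpec: sliding-window geometry
#'
#' @slot lengthS window length in seconds.
#' @slot stepS hop between consecutive window starts in seconds,
#'   `0 < stepS <= lengthS`.
#' @export
setClass("WindowSpec", representation(lengthS = "numeric", stepS = "numeric"))

setValidity("WindowSpec", function(object) {
  if (object@lengthS <= 0) return("window length must be positive")
  if (object@stepS <= 0 || object@stepS > object@lengthS)
    return("need 0 < step <= length")
  TRUE
})

#' @param lengthS window length in seconds.
#' @param stepS hop in seconds (defaults to `lengthS`, non-overlapping).
#' @rdname WindowSpec-class
#' @export
windowSpec <- function(lengthS, stepS = lengthS)
  new("WindowSpec", lengthS = as.numeric(lengthS), stepS = as.numeric(stepS))

setMethod("show", "WindowSpec", function(object)
  cat(sprintf("WindowSpec: length %g s, step %g s\n",
              object@lengthS, object@stepS)))

#' PulseParams: parameters of the in-silico pulse generator
#'
#' One beat of nominal period `period` rises from `offset` to
#' `offset + amplitude` over the upstroke fraction `upstrokeFrac` of the
#' beat (half-cosine ramp) and decays back following a power law with
#' exponent `concavity` (`1` = straight downstroke, larger = more concave).
#' Per-beat period, amplitude and upstroke-fraction jitters are i.i.d.
#' Gaussian (relative sd), truncated at 4 sd. Baseline wander (slow
#' sinusoid), linear drift and additive white noise are applied on top.
#'
#' @slot period mean beat period in s (`> 0`).
#' @slot amplitude mean pulse amplitude in signal units (`> 0`).
#' @slot upstrokeFrac upstroke fraction of the beat, in (0, 1).
#' @slot concavity downstroke concavity exponent, `>= 1`.
#' @slot sdPeriod,sdAmplitude,sdUpstroke relative per-beat jitters (sd).
#' @slot wanderAmp,wanderFreq baseline sinusoid amplitude (units) and
#'   frequency (Hz).
#' @slot driftRate linear drift in units/s.
#' @slot noiseSd additive white noise sd in signal units.
#' @slot offset baseline level in signal units.
#' @slot seed RNG seed (integer).
#' @export
setClass("PulseParams",
  representation(period = "numeric", amplitude = "numeric",
                 upstrokeFrac = "numeric", concavity = "numeric",
                 sdPeriod = "numeric", sdAmplitude = "numeric",
                 sdUpstroke = "numeric", wanderAmp = "numeric",
                 wanderFreq = "numeric", driftRate = "numeric",
                 noiseSd = "numeric", offset = "numeric", seed = "integer"))

setValidity("PulseParams", function(object) {
  msg <- character()
  if (object@period <= 0) msg <- c(msg, "period must be > 0")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (object@upstrokeFrac <= 0 || object@upstrokeFrac >= 1)
    msg <- c(msg, "upstrokeFrac must lie in (0, 1)")
  if (object@concavity < 1) msg <- c(msg, "concavity must be >= 1")
  if (any(c(object@sdPeriod, object@sdAmplitude, object@sdUpstroke,
            object@noiseSd) < 0))
    msg <- c(msg, "jitter and noise sds must be >= 0")
  if (object@sdPeriod >= 0.25)
    msg <- c(msg, "sdPeriod must be < 0.25 so every truncated draw keeps period > 0")
  if (length(msg)) msg else TRUE
})

#' @param period,amplitude,upstrokeFrac,concavity see slots.
#' @param sdPeriod,sdAmplitude,sdUpstroke relative per-beat jitter sds.
#' @param wanderAmp,wanderFreq,driftRate,noiseSd,offset,seed see slots.
#' @rdname PulseParams-class
#' @export
pulseParams <- function(period = 1, amplitude = 40, upstrokeFrac = 0.2,
                        concavity = 1.5, sdPeriod = 0, sdAmplitude = 0,
                        sdUpstroke = 0, wanderAmp = 0, wanderFreq = 0.1,
                        driftRate = 0, noiseSd = 0, offset = 80, seed = 1L) {
  new("PulseParams", period = as.numeric(period),
      amplitude = as.numeric(amplitude),
      upstrokeFrac = as.numeric(upstrokeFrac),
      concavity = as.numeric(concavity), sdPeriod = as.numeric(sdPeriod),
      sdAmplitude = as.numeric(sdAmplitude),
      sdUpstroke = as.numeric(sdUpstroke), wanderAmp = as.numeric(wanderAmp),
      wanderFreq = as.numeric(wanderFreq), driftRate = as.numeric(driftRate),
      noiseSd = as.numeric(noiseSd), offset = as.numeric(offset),
      seed = as.integer(seed))
}

setMethod("show", "PulseParams", function(object) {
  cat(sprintf(paste0(
    "PulseParams: period %g s (HR %.0f bpm), amplitude %g, upstroke %g,",
    " concavity %g\n  jitter sd (T, A, alpha): %g %g %g;",
    " wander %g @ %g Hz; drift %g/s; noise sd %g; offset %g; seed %d\n"),
    object@period, 60 / object@period, object@amplitude,
    object@upstrokeFrac, object@concavity, object@sdPeriod,
    object@sdAmplitude, object@sdUpstroke, object@wanderAmp,
    object@wanderFreq, object@driftRate, object@noiseSd, object@offset,
    object@seed))
})

#' CycleEstimate: average cycle length of a window
#'
#' @slot period estimated average cycle length in seconds.
#' @slot score normalized autocorrelation value at the chosen peak,
#'   in `[-1, 1]`.
#' @slot searchRange the `(Tmin, Tmax)` lag range searched, in seconds.
#' @export
setClass("CycleEstimate",
  representation(period = "numeric", score = "numeric",
                 searchRange = "numeric"))

setValidity("CycleEstimate", function(object) {
  if (object@score > 1 + 1e-9) return("score must be <= 1")
  if (object@period < object@searchRange[1] - 1e-9 ||
      object@period > object@searchRange[2] + 1e-9)
    return("period must lie within the search range")
  TRUE
})

setMethod("show", "CycleEstimate", function(object)
  cat(sprintf("CycleEstimate: T = %.5f s (HR %.1f bpm), score %.3f, range [%g, %g] s\n",
              object@period, 60 / object@period, object@score,
              object@searchRange[1], object@searchRange[2])))

#' Trajectory3: 3D delay-coordinate trajectory
#'
#' Rows are delay triples `(x(t_k), x(t_k - tau), x(t_k - 2 tau))` built
#' from a uniformly sampled signal; off-grid delayed values are linearly
#' interpolated.
#'
#' @slot x,y,z equal-length coordinate vectors (`y`, `z` are the lagged
#'   copies).
#' @slot tau delay in seconds.
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first emitted triple, in seconds.
#' @export
setClass("Trajectory3",
  representation(x = "numeric", y = "numeric", z = "numeric",
                 tau = "numeric", fs = "numeric", t0 = "numeric"))

setValidity("Trajectory3", function(object) {
  if (length(object@x) != length(object@y) ||
      length(object@x) != length(object@z))
    return("x, y, z must have equal length")
  if (object@tau <= 0) return("tau must be positive")
  TRUE
})

setMethod("show", "Trajectory3", function(object)
  cat(sprintf("Trajectory3: %d points, tau = %.5f s, fs = %g Hz\n",
              length(object@x), object@tau, object@fs)))

#' UVWSeries: trajectory in baseline/morphology coordinates
#'
#' Orthonormal rotation of a [Trajectory3-class]: `u` lies along the
#' `(1,1,1)` diagonal and carries the baseline level, `(v, w)` span the
#' orthogonal morphology plane ("viewing the cube down one corner").
#' The map preserves norms: `u^2 + v^2 + w^2 = x^2 + y^2 + z^2`.
#'
#' @slot u,v,w equal-length coordinate vectors.
#' @slot tau delay in seconds.
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first point, in seconds.
#' @export
setClass("UVWSeries",
  representation(u = "numeric", v = "numeric", w = "numeric",
                 tau = "numeric", fs = "numeric", t0 = "numeric"))

setValidity("UVWSeries", function(object) {
  if (length(object@u) != length(object@v) ||
      length(object@u) != length(object@w))
    return("u, v, w must have equal length")
  if (object@tau <= 0) return("tau must be positive")
  TRUE
})

setMethod("show", "UVWSeries", function(object)
  cat(sprintf("UVWSeries: %d points, tau = %.5f s, fs = %g Hz\n",
              length(object@u), object@tau, object@fs)))

#' DensityGrid: normalized 2D histogram of the (v, w) attractor
#'
#' @slot rho `n x n` matrix of non-negative cell masses summing to 1.
#'   Rows index `v` bins, columns index `w` bins; the grid spans
#'   `[-extent, extent]` in both coordinates.
#' @slot extent symmetric square half-width `B` in signal units.
#' @slot n grid resolution (`>= 32`).
#' @aliases densityMatrix gridExtent
#' @export
setClass("DensityGrid",
  representation(rho = "matrix", extent = "numeric", n = "integer"))

setValidity("DensityGrid", function(object) {
  if (object@n < 32L) return("grid resolution n must be >= 32")
  if (nrow(object@rho) != object@n || ncol(object@rho) != object@n)
    return("rho must be an n x n matrix")
  if (any(object@rho < 0)) return("density must be non-negative")
  if (abs(sum(object@rho) - 1) > 1e-9)
    return("density must be normalized to sum 1")
  if (object@extent <= 0) return("extent must be positive")
  TRUE
})

#' @rdname DensityGrid-class
#' @export
setMethod("densityMatrix", "DensityGrid", function(object) object@rho)

#' @rdname DensityGrid-class
#' @export
setMethod("gridExtent", "DensityGrid", function(object) object@extent)

setMethod("show", "DensityGrid", function(object)
  cat(sprintf("DensityGrid: %d x %d, extent [%.4g, %.4g], occupied cells %d\n",
              object@n, object@n, -object@extent, object@extent,
              sum(object@rho > 0))))

#' AttractorFeatures: scalar feature bundle for one window
#'
#' @slot period average cycle length T in seconds.
#' @slot hr heart rate `60 / T` in bpm (full precision).
#' @slot size attractor size S in signal units (proportional to pulse
#'   pressure; calibrated so the ideal calibration waveform recovers its
#'   amplitude).
#' @slot rotation triangular rotation angle in degrees in `(-60, 60]`;
#'   positive is counter-clockwise, clockwise rotation (more concave
#'   downstroke) is negative.
#' @slot armWidths RMS widths of the three attractor sides, signal units;
#'   arm 1 is the sector containing the positive-v axis after de-rotation.
#' @slot edgeCV coefficient of variation of density along each side.
#' @slot periodicity mean arm width / size (dimensionless; smaller = more
#'   periodic waveform).
#' @slot uMean window mean of the raw signal (from the u coordinate).
#' @slot uTrend least-squares slope of the baseline, units/s.
#' @slot extent density-grid half-width used for this window.
#' @slot flag `"ok"` or a failure/quality message.
#' @export
setClass("AttractorFeatures",
  representation(period = "numeric", hr = "numeric", size = "numeric",
                 rotation = "numeric", armWidths = "numeric",
                 edgeCV = "numeric", periodicity = "numeric",
                 uMean = "numeric", uTrend = "numeric", extent = "numeric",
                 flag = "character"))

setMethod("show", "AttractorFeatures", function(object) {
  cat(sprintf(paste0(
    "AttractorFeatures [%s]\n  T = %.4f s  HR = %.1f bpm  size = %.4g\n",
    "  rotation = %+.2f deg  arm widths = %s\n",
    "  edge CV = %s  periodicity = %.4g\n",
    "  u mean = %.4g  u trend = %.4g /s\n"),
    object@flag, object@period, object@hr, object@size, object@rotation,
    paste(sprintf("%.4g", object@armWidths), collapse = " "),
    paste(sprintf("%.3g", object@edgeCV), collapse = " "),
    object@periodicity, object@uMean, object@uTrend))
})

#' @param x an `AttractorFeatures` object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @rdname AttractorFeatures-class
#' @export
as.data.frame.AttractorFeatures <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(T_s = x@period, HR_bpm = x@hr, size = x@size,
             rotation_deg = x@rotation,
             arm1_width = x@armWidths[1], arm2_width = x@armWidths[2],
             arm3_width = x@armWidths[3],
             edge_cv1 = x@edgeCV[1], edge_cv2 = x@edgeCV[2],
             edge_cv3 = x@edgeCV[3],
             periodicity = x@periodicity, u_mean = x@uMean,
             u_trend = x@uTrend, extent = x@extent, flag = x@flag,
             stringsAsFactors = FALSE)
}
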