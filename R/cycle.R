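## Average cycle length via a normalized autocorrelation-like statistic.

#' Estimate the average cycle length of a window
#'
#' Computes, for every candidate lag in `[tMin, tMax]`, the Pearson
#' correlation between the leading part of the mean-removed window and its
#' lag-shifted copy, using a fixed overlap length (the window minus the
#' largest lag) so that every lag is scored on the same number of sample
#' pairs. Candidate periods are the local maxima of this correlation
#' curve; to avoid locking onto a harmonic, the smallest candidate whose
#' score reaches `guard` times the best score in range is selected and
#' refined to sub-sample precision by quadratic interpolation through the
#' peak and its two neighbours. The estimate uses the entire waveform
#' rather than detected peaks, so it is robust to baseline wander.
#'
#' @param signal a [PulseSignal-class] of duration at least `3 * tMax`.
#' @param tMin,tMax lag search range in seconds, `0 < tMin < tMax`.
#' @param guard harmonic-guard fraction in (0, 1]; default 0.8.
#' @return a [CycleEstimate-class].
#' @examples
#' sig <- generatePulseTrain(pulseParams(period = 0.8), 10, 250)
#' estimateCycleLength(sig, 0.2, 2)
#' @export
estimateCycleLength <- function(signal, tMin = 60 / 300, tMax = 60 / 30,
                                guard = 0.8) {
  stopifnot(is(signal, "PulseSignal"))
  if (tMin <= 0 || tMin >= tMax) stop("need 0 < tMin < tMax")
  if (duration(signal) < 3 * tMax)
    stop("signal duration must be at least 3 * tMax (",
         format(3 * tMax), " s)")
  fs <- sampleRate(signal)
  x <- samples(signal) - mean(samples(signal))
  N <- length(x)
  kmin <- max(2L, as.integer(ceiling(tMin * fs)))
  kmax <- as.integer(floor(tMax * fs))
  if (kmax - kmin < 2L)
    stop("search range too narrow at this sampling rate")
  ks <- (kmin - 1L):(kmax + 1L)
  M <- N - (kmax + 1L)
  a <- x[seq_len(M)]
  sa <- sqrt(sum(a^2))
  r <- vapply(ks, function(k) {
    b <- x[(1L + k):(M + k)]
    sum(a * b) / (sa * sqrt(sum(b^2)))
  }, numeric(1))
  ## local maxima strictly inside the padded range
  loc <- which(diff(sign(diff(r))) < 0) + 1L
  loc <- loc[ks[loc] >= kmin & ks[loc] <= kmax]
  if (!length(loc)) stop("no periodicity detected in [",
                         format(tMin), ", ", format(tMax), "] s")
  best <- max(r[loc])
  pk <- min(loc[r[loc] >= guard * best])
  denom <- r[pk - 1L] - 2 * r[pk] + r[pk + 1L]
  d <- if (denom < 0) 0.5 * (r[pk - 1L] - r[pk + 1L]) / denom else 0
  d <- max(min(d, 0.5), -0.5)
  period <- (ks[pk] + d) / fs
  score <- min(r[pk] - 0.25 * (r[pk - 1L] - r[pk + 1L]) * d, 1)
  new("CycleEstimate", period = period, score = score,
      searchRange = c(tMin, tMax))
}

#' Heart rate from cycle length
#'
#' @param period average waveform cycle length in seconds (`> 0`).
#' @return heart rate in bpm, `60 / period`, at full precision; round for
#'   display (an 89 ms cycle equates to 674 bpm).
#' @examples
#' round(heartRateFromCycle(0.089))
#' @export
heartRateFromCycle <- function(period) {
  if (!is.numeric(period) || any(!is.finite(period)) || any(period <= 0))
    stop("period must be positive")
  60 / period
}
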