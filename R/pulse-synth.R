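## Parametric in-silico pulse generator.
##
## Beat i occupies [t_i, t_i + T_i). The upstroke is a half-cosine ramp
## from the offset to offset + A_i over alpha_i * T_i. The downstroke
## follows offset + A_i * (1 - s)^kappa where the normalized phase s uses
## the NOMINAL upstroke fraction, s = (p - alpha_i) / (1 - alpha), so that
## the downstroke template (shape and slope) is identical across beats
## when only the upstroke fraction jitters -- the manipulation where the
## upstroke gradient varies while total period and downstroke are fixed.
## When alpha_i != alpha the curve is clipped at the baseline (early
## runoff) or ends slightly above it (foot-level step of
## A_i (alpha_i - alpha) / (1 - alpha)); both coincide with the classic
## continuous form when sdUpstroke = 0.

## run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## iid N(0, sd) truncated (clamped) at +/- 4 sd; one draw per beat so the
## RNG stream is independent of the clamping
.truncNorm <- function(n, sd) {
  if (sd == 0) return(numeric(n) + stats::rnorm(n, 0, 0))
  pmin(pmax(stats::rnorm(n, 0, sd), -4 * sd), 4 * sd)
}

#' Generate an in-silico pulse train
#'
#' Deterministic given the seed stored in `params`. The returned signal
#' carries per-beat ground truth (realized period, amplitude and upstroke
#' fraction for every beat overlapping the record) retrievable with
#' [beatTruth()], plus the generating parameters, in its metadata.
#'
#' @param params a [PulseParams-class].
#' @param durationS record duration in seconds; must be at least 3 beat
#'   periods.
#' @param fs sampling rate in Hz; at least 20 samples per beat are
#'   required.
#' @return a [PulseSignal-class] of `round(fs * durationS)` samples.
#' @examples
#' sig <- generatePulseTrain(pulseParams(period = 1, amplitude = 40),
#'                           durationS = 10, fs = 250)
#' head(beatTruth(sig))
#' @export
generatePulseTrain <- function(params, durationS, fs) {
  stopifnot(is(params, "PulseParams"))
  Tm <- params@period
  if (durationS < 3 * Tm)
    stop("durationS must be at least 3 beat periods")
  if (fs * Tm < 20)
    stop("need at least 20 samples per beat (fs * period >= 20)")
  n <- samplesInWindow(fs, durationS)
  alpha <- params@upstrokeFrac
  kappa <- params@concavity
  ## enough beats to cover the record even with maximal negative jitter
  nb <- ceiling(durationS / (Tm * (1 - 4 * params@sdPeriod))) + 2L
  dat <- .withSeed(params@seed, {
    Ti <- Tm * (1 + .truncNorm(nb, params@sdPeriod))
    Ai <- params@amplitude * (1 + .truncNorm(nb, params@sdAmplitude))
    ai <- alpha * (1 + .truncNorm(nb, params@sdUpstroke))
    noise <- stats::rnorm(n, 0, params@noiseSd)
    list(Ti = Ti, Ai = pmax(Ai, .Machine$double.eps),
         ai = pmin(pmax(ai, 0.005), 0.995), noise = noise)
  })
  starts <- c(0, cumsum(dat$Ti))
  t <- (seq_len(n) - 1) / fs
  b <- findInterval(t, starts)
  p <- (t - starts[b]) / dat$Ti[b]
  s <- (p - dat$ai[b]) / (1 - alpha)
  x <- ifelse(p < dat$ai[b],
              dat$Ai[b] * (1 - cos(pi * p / dat$ai[b])) / 2,
              dat$Ai[b] * pmax(1 - s, 0)^kappa)
  x <- x + params@offset + dat$noise
  if (params@wanderAmp != 0)
    x <- x + params@wanderAmp * sin(2 * pi * params@wanderFreq * t)
  if (params@driftRate != 0)
    x <- x + params@driftRate * t
  used <- which(starts[seq_len(nb)] < durationS)
  beats <- data.frame(start_s = starts[used], period_s = dat$Ti[used],
                      amplitude = dat$Ai[used], upstroke_frac = dat$ai[used])
  pulseSignal(x, fs = fs, units = "arbitrary",
              metadata = list(beats = beats, params = params))
}

#' Add baseline wander and drift to a signal
#'
#' Adds `wanderAmp * sin(2 pi wanderFreq t) + driftRate * t` (absolute
#' time `t`). Length and sampling rate are unchanged. The wander should be
#' slow relative to the pulse: a warning is issued when the frequency
#' exceeds half the beat rate of a generated train (known from its ground
#' truth).
#'
#' @param signal a [PulseSignal-class].
#' @param wanderAmp sinusoid amplitude in signal units.
#' @param wanderFreq sinusoid frequency in Hz.
#' @param driftRate linear drift in units/s.
#' @return a [PulseSignal-class].
#' @export
addBaselineWander <- function(signal, wanderAmp = 0, wanderFreq = 0.1,
                              driftRate = 0) {
  stopifnot(is(signal, "PulseSignal"))
  bt <- beatTruth(signal)
  if (!is.null(bt) && wanderAmp != 0 &&
      wanderFreq > 0.5 / mean(bt$period_s))
    warning("wander frequency exceeds half the beat rate; ",
            "it will not separate from the pulse")
  tt <- sampleTimes(signal)
  x <- samples(signal) + wanderAmp * sin(2 * pi * wanderFreq * tt) +
    driftRate * tt
  pulseSignal(x, fs = sampleRate(signal), t0 = startTime(signal),
              units = signalUnits(signal), metadata = signal@metadata)
}
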