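## Shared fixture builders. Everything is generated in code; fixtures with
## the same arguments are cached per test run to keep the suite fast.

.fixtureCache <- new.env(parent = emptyenv())

## canonical ideal train: straight downstroke, 20% upstroke, unit-ish
## amplitude, no stochastic terms; periods chosen so fs * period is an
## integer (exact discrete periodicity)
idealTrain <- function(period = 1, amplitude = 1, fs = 500, duration = 20,
                       concavity = 1, offset = 0, seed = 1L, ...) {
  key <- paste0("ideal_", paste(c(period, amplitude, fs, duration,
                                  concavity, offset, seed, ...),
                                collapse = "_"))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generatePulseTrain(
      pulseParams(period = period, amplitude = amplitude,
                  upstrokeFrac = 0.2, concavity = concavity,
                  offset = offset, seed = seed, ...),
      durationS = duration, fs = fs)
  .fixtureCache[[key]]
}

jitterTrain <- function(sdPeriod = 0, sdAmplitude = 0, sdUpstroke = 0,
                        noiseSd = 0, period = 1, amplitude = 1, fs = 500,
                        duration = 60, concavity = 1, seed = 1L) {
  generatePulseTrain(
    pulseParams(period = period, amplitude = amplitude, upstrokeFrac = 0.2,
                concavity = concavity, sdPeriod = sdPeriod,
                sdAmplitude = sdAmplitude, sdUpstroke = sdUpstroke,
                noiseSd = noiseSd, offset = 0, seed = seed),
    durationS = duration, fs = fs)
}

## morphology-plane point cloud of the standard feature pipeline
## (cycle estimate, baseline correction, embedding at T/3)
pipelineUVW <- function(signal, tMin = 0.5, tMax = 2) {
  est <- estimateCycleLength(signal, tMin, tMax)
  corrected <- removeBaseline(signal, est@period)
  projectUVW(delayEmbed(corrected, est@period / 3))
}

## a UVWSeries built directly from (v, w) points (u unused)
uvwFromPoints <- function(v, w, fs = 100, tau = 1 / 3) {
  new("UVWSeries", u = numeric(length(v)), v = as.numeric(v),
      w = as.numeric(w), tau = tau, fs = fs, t0 = 0)
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / abs(expected), tol)
}
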