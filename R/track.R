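## Sliding-window feature tracking over long records.

.naFeatureRow <- function(msg) {
  data.frame(T_s = NA_real_, HR_bpm = NA_real_, size = NA_real_,
             rotation_deg = NA_real_, arm1_width = NA_real_,
             arm2_width = NA_real_, arm3_width = NA_real_,
             edge_cv1 = NA_real_, edge_cv2 = NA_real_, edge_cv3 = NA_real_,
             periodicity = NA_real_, u_mean = NA_real_, u_trend = NA_real_,
             extent = NA_real_, flag = msg, stringsAsFactors = FALSE)
}

#' Track attractor features through a long record
#'
#' Slides a window through every unmasked segment of the record and
#' computes the full [windowFeatures()] bundle per window, re-estimating
#' the cycle length each time so non-stationary heart rates are followed.
#' Each segment of duration `D` yields `floor((D - length)/step) + 1`
#' windows; windows where the pipeline fails (e.g. no periodicity) are
#' emitted with the failure message in `flag`, never dropped silently.
#'
#' @param signal a [PulseSignal-class].
#' @param spec a [WindowSpec-class]; the window must be at least
#'   `3 * tMax` of the configured search range.
#' @param mask an optional [ArtifactMask-class].
#' @param config a [featureConfig()] list.
#' @return a `data.frame` with one row per window: `window_start_s`,
#'   `window_end_s`, the feature columns of
#'   [as.data.frame.AttractorFeatures()], and `flag`.
#' @examples
#' sig <- generatePulseTrain(pulseParams(period = 0.8), 30, 250)
#' fs <- track(sig, windowSpec(10, 5))
#' fs[, c("window_start_s", "HR_bpm", "size")]
#' @export
track <- function(signal, spec, mask = NULL,
                  config = featureConfig("human")) {
  stopifnot(is(signal, "PulseSignal"), is(spec, "WindowSpec"))
  if (spec@lengthS < 3 * config$tMax)
    stop("window length must be at least 3 * tMax = ",
         format(3 * config$tMax), " s")
  segments <- if (is.null(mask)) list(signal)
              else applyMask(signal, mask)
  if (!length(segments)) stop("the mask removes the whole signal")
  fs <- sampleRate(signal)
  nwin <- samplesInWindow(fs, spec@lengthS)
  rows <- list()
  anyWindow <- FALSE
  for (seg in segments) {
    D <- duration(seg)
    if (D < spec@lengthS - 1e-9) next
    nw <- as.integer(floor((D - spec@lengthS) / spec@stepS + 1e-9)) + 1L
    for (k in seq_len(nw)) {
      ws <- startTime(seg) + (k - 1L) * spec@stepS
      i0 <- as.integer(round((ws - startTime(seg)) * fs)) + 1L
      win <- pulseSignal(samples(seg)[i0:(i0 + nwin - 1L)], fs = fs,
                         t0 = ws, units = signalUnits(seg))
      row <- tryCatch(as.data.frame(windowFeatures(win, config)),
                      error = function(e) .naFeatureRow(conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(window_start_s = ws,
                         window_end_s = ws + spec@lengthS), row)
      anyWindow <- TRUE
    }
  }
  if (!anyWindow)
    stop("window (", spec@lengthS, " s) is longer than every unmasked segment")
  do.call(rbind, rows)
}

#' Write a feature series as CSV
#'
#' One row per window with a header naming units
#' (seconds, bpm, signal units, degrees).
#'
#' @param featureSeries data.frame from [track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureSeries <- function(featureSeries, path) {
  utils::write.csv(featureSeries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
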