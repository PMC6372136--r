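## Reading/writing waveform files and artifact-mask arithmetic.

#' Read a waveform from delimited text
#'
#' Accepts either a two-column file (`time,value`, seconds and signal
#' units) or a value-only file, in which case `fs` must be given. The
#' delimiter (comma, tab or whitespace) and an optional header line are
#' detected automatically. A time column must be uniform: the sampling
#' rate is inferred from the median time step, and any step deviating from
#' it by more than 1 ppm (relative) is an error naming the worst gap.
#'
#' @param path path to a delimited text file (UTF-8, decimal point `.`).
#' @param fs sampling rate in Hz; required for value-only files, and when
#'   given alongside a time column it overrides the inferred rate (the
#'   grid must still be uniform).
#' @param column name or index of the value column; by default the second
#'   column when a time column is present, otherwise the first.
#' @param units unit label to attach.
#' @return a [PulseSignal-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeSignal(pulseSignal(sin(1:100), fs = 125), tf)
#' readSignal(tf)
#' @export
readSignal <- function(path, fs = NULL, column = NULL, units = "arbitrary") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (!ncol(df)) stop("no columns found in ", path)
  hasTime <- ncol(df) >= 2L
  if (!is.null(column)) {
    vcol <- if (is.character(column)) {
      if (!column %in% names(df)) stop("no column named '", column, "'")
      match(column, names(df))
    } else as.integer(column)
    ## an explicit value column in a multi-column file keeps column 1 as time
    hasTime <- ncol(df) >= 2L && vcol != 1L
  } else {
    vcol <- if (hasTime) 2L else 1L
  }
  vals <- as.numeric(df[[vcol]])
  if (anyNA(vals)) stop("non-numeric values in column ", vcol)
  t0 <- 0
  if (hasTime) {
    tt <- as.numeric(df[[1L]])
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    med <- stats::median(dt)
    rel <- abs(dt - med) / med
    if (any(rel > 1e-6)) {
      k <- which.max(rel)
      stop(sprintf(paste0("non-uniform time grid: step of %.9g s between ",
                          "t = %.9g and t = %.9g (expected %.9g s)"),
                   dt[k], tt[k], tt[k + 1L], med))
    }
    if (is.null(fs)) fs <- 1 / med
    t0 <- tt[1L]
  } else if (is.null(fs)) {
    stop("value-only file: the sampling rate 'fs' must be given")
  }
  pulseSignal(vals, fs = fs, t0 = t0, units = units)
}

#' Write a waveform as two-column CSV
#'
#' Writes `time,value` with 17 significant digits so that a
#' read/write cycle round-trips samples bit-exactly.
#'
#' @param signal a [PulseSignal-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSignal <- function(signal, path) {
  stopifnot(is(signal, "PulseSignal"))
  tt <- sampleTimes(signal)
  lines <- c("time,value",
             sprintf("%.17g,%.17g", tt, samples(signal)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an artifact mask from CSV
#'
#' Expects two columns (`start`, `end`) in seconds, with or without a
#' header.
#'
#' @param path path to a delimited text file.
#' @return an [ArtifactMask-class].
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(path, header = header, sep = sep)
  if (ncol(df) < 2L) stop("mask file needs two columns: start,end")
  artifactMask(as.numeric(df[[1L]]), as.numeric(df[[2L]]))
}

#' Number of samples spanned by a duration
#'
#' @param fs sampling rate in Hz (`> 0`).
#' @param durationS duration in seconds (`> 0`).
#' @return `round(fs * durationS)`; e.g. a 10 s window of a 125 Hz monitor
#'   holds 1250 samples.
#' @examples
#' samplesInWindow(125, 10)
#' @export
samplesInWindow <- function(fs, durationS) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (!is.finite(durationS) || durationS <= 0)
    stop("durationS must be positive")
  as.integer(round(fs * durationS))
}

#' Split a signal into unmasked segments
#'
#' Removes the masked half-open intervals `[start, end)` and returns the
#' remaining contiguous runs as separate signals with correct start times.
#' Sample `i` (at time `t0 + (i-1)/fs`) is masked when that time falls in
#' a mask interval.
#'
#' @param signal a [PulseSignal-class].
#' @param mask an [ArtifactMask-class]; intervals must lie within the
#'   signal's time span.
#' @param minDuration segments shorter than this many seconds are flagged
#'   with a `"short"` attribute (not dropped); default 0 flags nothing.
#' @return list of [PulseSignal-class] segments (possibly empty). The sum
#'   of segment lengths plus the number of masked samples equals the input
#'   length.
#' @export
applyMask <- function(signal, mask, minDuration = 0) {
  stopifnot(is(signal, "PulseSignal"), is(mask, "ArtifactMask"))
  iv <- maskIntervals(mask)
  t1 <- startTime(signal) + duration(signal)
  if (nrow(iv) &&
      (any(iv[, 1] < startTime(signal) - 1e-9) || any(iv[, 2] > t1 + 1e-9)))
    stop("mask interval outside the signal's time span")
  tt <- sampleTimes(signal)
  masked <- rep(FALSE, length(tt))
  for (r in seq_len(nrow(iv)))
    masked <- masked | (tt >= iv[r, 1] & tt < iv[r, 2])
  keep <- !masked
  if (!any(keep)) return(list())
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (j in which(runs$values)) {
    seg <- pulseSignal(samples(signal)[starts[j]:ends[j]],
                       fs = sampleRate(signal),
                       t0 = tt[starts[j]], units = signalUnits(signal))
    if (minDuration > 0 && duration(seg) < minDuration)
      attr(seg, "short") <- TRUE
    out[[length(out) + 1L]] <- seg
  }
  out
}
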