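## Quantification of the 2D attractor: density, size, rotation, arm
## widths, edge uniformity, periodicity and baseline statistics.

#' 2D histogram density of the (v, w) attractor
#'
#' Bins the morphology-plane points on a symmetric square grid
#' `[-B, B]^2` and normalizes to total mass 1. Points exactly on the
#' upper edge fall into the last bin; with a caller-fixed extent, points
#' outside the square are dropped before normalization.
#'
#' @param uvw a [UVWSeries-class] with at least 100 points.
#' @param n grid resolution (`>= 32`); default 128.
#' @param extent half-width `B`; default `1.05 *` the largest point
#'   radius of the window (auto-scaled). Fix it explicitly when densities
#'   of different windows must be comparable.
#' @return a [DensityGrid-class].
#' @export
density2d <- function(uvw, n = 128L, extent = NULL) {
  stopifnot(is(uvw, "UVWSeries"))
  v <- uvw@v; w <- uvw@w
  if (length(v) < 100L)
    stop("need at least 100 points to form a density")
  n <- as.integer(n)
  B <- if (is.null(extent)) {
    r <- max(sqrt(v^2 + w^2))
    if (r == 0) 1 else 1.05 * r
  } else as.numeric(extent)
  inb <- v >= -B & v <= B & w >= -B & w <= B
  v <- v[inb]; w <- w[inb]
  if (!length(v)) stop("no points inside the requested extent")
  iv <- pmin(1L + as.integer(floor((v + B) / (2 * B) * n)), n)
  iw <- pmin(1L + as.integer(floor((w + B) / (2 * B) * n)), n)
  rho <- matrix(tabulate(iv + n * (iw - 1L), nbins = n * n), n, n)
  rho <- rho / sum(rho)
  new("DensityGrid", rho = rho, extent = B, n = n)
}

## cell-centre coordinate vector of a grid
.gridCentres <- function(grid) {
  B <- grid@extent; n <- grid@n
  -B + (2 * B) * (seq_len(n) - 0.5) / n
}

## rotate a density by `deg` about the origin with bilinear resampling:
## each target cell samples the source density at the back-rotated centre
.rotateGrid <- function(grid, deg) {
  n <- grid@n; B <- grid@extent
  cc <- .gridCentres(grid)
  V <- matrix(cc, n, n)
  W <- matrix(cc, n, n, byrow = TRUE)
  a <- -deg * pi / 180
  vs <- cos(a) * V - sin(a) * W
  ws <- sin(a) * V + cos(a) * W
  ## fractional cell indices of the source points
  fi <- (vs + B) / (2 * B) * n + 0.5
  fj <- (ws + B) / (2 * B) * n + 0.5
  i0 <- floor(fi); j0 <- floor(fj)
  di <- fi - i0; dj <- fj - j0
  at <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    out <- numeric(length(i))
    out[ok] <- grid@rho[cbind(i[ok], j[ok])]
    out
  }
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  out <- at(i0, j0) * (1 - di) * (1 - dj) +
    at(i0 + 1L, j0) * di * (1 - dj) +
    at(i0, j0 + 1L) * (1 - di) * dj +
    at(i0 + 1L, j0 + 1L) * di * dj
  matrix(out, n, n)
}

#' Three-fold symmetrization of a density
#'
#' Averages the density with its rotations by 120 and 240 degrees about
#' the origin (bilinear resampling) and renormalizes -- the averaging of
#' the triangular attractor that underlies the size measurement. The
#' operation is idempotent up to resampling tolerance, and leaves any
#' three-fold-symmetric density unchanged.
#'
#' @param density a [DensityGrid-class].
#' @return a [DensityGrid-class] on the same grid.
#' @export
symmetrize <- function(density) {
  stopifnot(is(density, "DensityGrid"))
  rho <- (density@rho + .rotateGrid(density, 120) +
            .rotateGrid(density, 240)) / 3
  rho <- pmax(rho, 0)
  rho <- rho / sum(rho)
  new("DensityGrid", rho = rho, extent = density@extent, n = density@n)
}

#' Attractor size (pulse-pressure scale)
#'
#' `S = c0 * q95(r)` where `r` are the radial distances of the
#' morphology-plane points from the origin (replicating each point at its
#' three 120-degree rotations, which leaves radii unchanged) and `c0` is
#' a fixed calibration constant chosen once so that the ideal periodic
#' calibration waveform recovers its pulse amplitude (see
#' [calibration()]). Size is homogeneous (`S(k x) = k S(x)`), invariant
#' to constant offsets, and directly proportional to pulse pressure.
#'
#' @param uvw a [UVWSeries-class] with at least 100 points.
#' @param probs quantile of the radius distribution; default 0.95
#'   (robust to the diffuse tails of noisy windows).
#' @return size in signal units; 0 for a degenerate (single-point) cloud.
#' @export
attractorSize <- function(uvw, probs = 0.95) {
  stopifnot(is(uvw, "UVWSeries"))
  v <- uvw@v; w <- uvw@w
  if (length(v) < 100L) stop("need at least 100 points")
  if (max(v) - min(v) == 0 && max(w) - min(w) == 0) return(0)
  r <- sqrt(v^2 + w^2)
  calibration()$c0 * as.numeric(stats::quantile(r, probs))
}

## order-3 angular moment sum(rho * exp(3i * phi)) over cell centres
.order3Moment <- function(grid) {
  n <- grid@n
  cc <- .gridCentres(grid)
  V <- matrix(cc, n, n)
  W <- matrix(cc, n, n, byrow = TRUE)
  phi <- atan2(W, V)
  sum(grid@rho * exp(3i * phi))
}

#' Rotation angle of the triangular attractor
#'
#' One third of the argument of the order-3 angular moment of the
#' density, referenced so that the ideal calibration waveform sits at 0
#' and wrapped to `(-60, 60]`. Positive angles are counter-clockwise; a
#' more concave downstroke rotates the attractor clockwise (negative).
#' The statistic is exactly equivariant: rotating the point cloud by
#' `delta` adds `delta` to the angle.
#'
#' @param density a [DensityGrid-class].
#' @return rotation in degrees in `(-60, 60]`.
#' @export
rotationAngle <- function(density) {
  stopifnot(is(density, "DensityGrid"))
  m3 <- .order3Moment(density)
  if (Mod(m3) < 1e-6)
    stop("no triangular orientation: order-3 moment magnitude ",
         format(Mod(m3)))
  raw <- Arg(m3) / 3 * 180 / pi
  .wrapAngle(raw - calibration()$thetaRef)
}

#' Arm widths and edge-density uniformity
#'
#' De-rotates the point cloud by `-theta` into the reference orientation
#' and partitions it by angle into three 120-degree sectors centred on
#' the canonical side directions of the calibration triangle; arm 1 is
#' the sector containing the positive-v axis. Each sector's points are
#' fitted with a total-least-squares line; the arm width is the RMS
#' perpendicular distance to that line, and the edge uniformity is the
#' coefficient of variation of point counts in 20 equal-length bins along
#' the line (over the 5th-95th percentile span). A perfectly periodic
#' waveform has razor-thin arms (width well below 1% of the size); beat
#' to beat variability of a specific waveform segment widens a specific
#' arm.
#'
#' @param uvw a [UVWSeries-class] with at least 300 points.
#' @param theta rotation angle in degrees, from [rotationAngle()].
#' @return list with `widths` and `edgeCV`, numeric length-3 vectors in
#'   fixed sector order (NA for sectors with fewer than 30 points).
#' @export
armWidths <- function(uvw, theta) {
  stopifnot(is(uvw, "UVWSeries"))
  v <- uvw@v; w <- uvw@w
  if (length(v) < 300L) stop("need at least 300 points")
  a <- -theta * pi / 180
  vr <- cos(a) * v - sin(a) * w
  wr <- sin(a) * v + cos(a) * w
  phi <- atan2(wr, vr) * 180 / pi
  centres <- calibration()$sideAngles
  widths <- rep(NA_real_, 3)
  edgeCV <- rep(NA_real_, 3)
  for (s in 1:3) {
    dd <- abs(.wrapAngle(phi - centres[s], full = TRUE))
    sel <- dd < 60
    if (sum(sel) < 30L) next
    pv <- vr[sel]; pw <- wr[sel]
    mv <- mean(pv); mw <- mean(pw)
    cvv <- cbind(pv - mv, pw - mw)
    eg <- eigen(crossprod(cvv) / nrow(cvv), symmetric = TRUE)
    widths[s] <- sqrt(max(eg$values[2], 0))
    ## positions along the fitted line (major axis direction)
    tpos <- cvv %*% eg$vectors[, 1]
    qs <- stats::quantile(tpos, c(0.05, 0.95))
    if (diff(qs) > 0) {
      inb <- tpos >= qs[1] & tpos <= qs[2]
      counts <- tabulate(pmin(1L + as.integer(
        floor((tpos[inb] - qs[1]) / diff(qs) * 20)), 20L), nbins = 20L)
      edgeCV[s] <- stats::sd(counts) / mean(counts)
    } else edgeCV[s] <- 0
  }
  list(widths = widths, edgeCV = edgeCV)
}

#' Waveform periodicity score
#'
#' Mean available arm width divided by attractor size. A perfectly
#' periodic waveform scores 0; larger values mean a more diffuse
#' attractor, i.e. a less repeatable waveform.
#'
#' @param widths numeric vector of arm widths (NAs ignored).
#' @param size attractor size (`> 0`).
#' @return dimensionless score `>= 0`.
#' @export
periodicityScore <- function(widths, size) {
  if (!is.finite(size) || size <= 0) stop("size must be positive")
  if (all(is.na(widths))) return(NA_real_)
  mean(widths, na.rm = TRUE) / size
}

#' Baseline statistics from the u coordinate
#'
#' `uMean` is `mean(u)/sqrt(3)`, which equals the window mean of the raw
#' signal; `uTrend` is the least-squares slope of `u/sqrt(3)` against
#' time in units/s. Together they track slow systolic/diastolic level
#' changes that the morphology plane deliberately ignores.
#'
#' @param uvw a [UVWSeries-class] with at least 2 points.
#' @return list with `uMean` and `uTrend`.
#' @export
uStatistics <- function(uvw) {
  stopifnot(is(uvw, "UVWSeries"))
  u <- uvw@u / sqrt(3)
  if (length(u) < 2L) stop("need at least 2 points")
  tt <- (seq_along(u) - 1) / uvw@fs
  tc <- tt - mean(tt)
  list(uMean = mean(u), uTrend = sum(tc * (u - mean(u))) / sum(tc^2))
}

#' Feature-extraction configuration
#'
#' Bundles the tunable constants of the pipeline. Species presets set the
#' cycle-length search range and default window geometry: `"human"`
#' searches 60/300 to 60/30 s (30-300 bpm, 10 s windows), `"mouse"`
#' 60/800 to 60/300 s (300-800 bpm, 2 s windows).
#'
#' @param species `"human"` or `"mouse"`, or `NULL` to keep the explicit
#'   ranges.
#' @param tMin,tMax cycle-length search range in seconds.
#' @param tauFraction delay as a fraction of the cycle length; default
#'   1/3 (the three-fold symmetric triangular attractor).
#' @param harmonicGuard fundamental-vs-harmonic guard threshold.
#' @param gridN density resolution.
#' @param fixedExtent fixed density half-width, or `NULL` for per-window
#'   auto-scaling.
#' @param baselineCycles width of the baseline-trend window in periods.
#' @param windowS,stepS default tracking window length and hop in
#'   seconds.
#' @return named list of settings.
#' @export
featureConfig <- function(species = c("human", "mouse"), tMin = NULL,
                          tMax = NULL, tauFraction = 1 / 3,
                          harmonicGuard = 0.8, gridN = 128L,
                          fixedExtent = NULL, baselineCycles = 3,
                          windowS = NULL, stepS = NULL) {
  preset <- switch(match.arg(species),
    human = list(tMin = 60 / 300, tMax = 60 / 30, windowS = 10, stepS = 5),
    mouse = list(tMin = 60 / 800, tMax = 60 / 300, windowS = 2, stepS = 1))
  list(species = match.arg(species),
       tMin = if (is.null(tMin)) preset$tMin else tMin,
       tMax = if (is.null(tMax)) preset$tMax else tMax,
       tauFraction = tauFraction, harmonicGuard = harmonicGuard,
       gridN = as.integer(gridN), fixedExtent = fixedExtent,
       baselineCycles = baselineCycles,
       windowS = if (is.null(windowS)) preset$windowS else windowS,
       stepS = if (is.null(stepS)) preset$stepS else stepS)
}

#' Full attractor feature bundle for one window
#'
#' Runs the complete pipeline on one window: cycle-length estimation,
#' delay embedding at `tau = tauFraction * T`, baseline-trend removal
#' before the morphology embedding (the u statistics use the raw,
#' uncorrected embedding so absolute level and trend are preserved),
#' density, size, rotation, arm widths, edge uniformity and periodicity.
#'
#' @param signal a [PulseSignal-class] window.
#' @param config a [featureConfig()] list.
#' @return an [AttractorFeatures-class].
#' @examples
#' sig <- generatePulseTrain(pulseParams(period = 0.8), 10, 250)
#' windowFeatures(sig, featureConfig("human"))
#' @export
windowFeatures <- function(signal, config = featureConfig("human")) {
  est <- estimateCycleLength(signal, config$tMin, config$tMax,
                             config$harmonicGuard)
  Tw <- est@period
  tau <- config$tauFraction * Tw
  corrected <- removeBaseline(signal, Tw, config$baselineCycles)
  uvwC <- projectUVW(delayEmbed(corrected, tau))
  uvwRaw <- projectUVW(delayEmbed(signal, tau))
  size <- attractorSize(uvwC)
  dens <- density2d(uvwC, n = config$gridN, extent = config$fixedExtent)
  theta <- rotationAngle(dens)
  arms <- armWidths(uvwC, theta)
  us <- uStatistics(uvwRaw)
  new("AttractorFeatures", period = Tw, hr = heartRateFromCycle(Tw),
      size = size, rotation = theta, armWidths = arms$widths,
      edgeCV = arms$edgeCV,
      periodicity = periodicityScore(arms$widths, size),
      uMean = us$uMean, uTrend = us$uTrend, extent = gridExtent(dens),
      flag = "ok")
}
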