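test_that("density2d matches a brute-force per-point binning oracle", {
  set.seed(21)
  r <- sqrt(runif(10000)); a <- runif(10000, 0, 2 * pi)
  uvw <- uvwFromPoints(r * cos(a), r * sin(a))
  grid <- density2d(uvw, n = 64L)
  B <- gridExtent(grid); n <- 64L
  ## independent double-loop binning
  ref <- matrix(0, n, n)
  for (k in seq_len(10000)) {
    i <- min(1 + floor((uvw@v[k] + B) / (2 * B) * n), n)
    j <- min(1 + floor((uvw@w[k] + B) / (2 * B) * n), n)
    ref[i, j] <- ref[i, j] + 1
  }
  ref <- ref / sum(ref)
  expect_identical(densityMatrix(grid), ref)
  expect_lt(abs(sum(densityMatrix(grid)) - 1), 1e-12)
})

test_that("density2d edge cases: coincident points, fixed extent, minimum n", {
  pts <- uvwFromPoints(rep(0.3, 200), rep(-0.2, 200))
  g <- density2d(pts, n = 32L)
  expect_identical(sum(densityMatrix(g) == 1), 1L)  # one cell holds all mass

  ## caller-fixed extent drops points outside but keeps normalization
  set.seed(3)
  far <- uvwFromPoints(c(rnorm(150, 0, 0.1), 5), c(rnorm(150, 0, 0.1), 5))
  gf <- density2d(far, n = 32L, extent = 1)
  expect_lt(abs(sum(densityMatrix(gf)) - 1), 1e-12)

  expect_error(density2d(uvwFromPoints(1:50, 1:50)), "100")
  expect_error(density2d(pts, n = 16L), "32")
})

test_that("symmetrize preserves three-fold-symmetric densities", {
  n <- 128L; B <- 1
  cc <- -B + 2 * B * (seq_len(n) - 0.5) / n
  g <- outer(cc, cc, function(v, w) exp(-(v^2 + w^2) / (2 * 0.25^2)))
  gauss <- new("DensityGrid", rho = g / sum(g), extent = B, n = n)
  out <- symmetrize(gauss)
  expect_lt(max(abs(densityMatrix(out) - densityMatrix(gauss))), 1e-6)
})

test_that("symmetrize spreads one off-origin cell into three equal blobs", {
  n <- 128L
  rho <- matrix(0, n, n)
  rho[96, 64] <- 1  # on the positive-v axis, radius ~ 0.49
  g <- new("DensityGrid", rho = rho, extent = 1, n = n)
  out <- symmetrize(g)
  m <- densityMatrix(out)
  blobMass <- function(i, j) sum(m[max(1, i - 2):min(n, i + 2),
                                   max(1, j - 2):min(n, j + 2)])
  ## original cell centre rotated by 0/120/240 degrees
  cc <- -1 + 2 * (c(96, 64) - 0.5) / n
  for (ang in c(0, 120, 240) * pi / 180) {
    vc <- cos(ang) * cc[1] - sin(ang) * cc[2]
    wc <- sin(ang) * cc[1] + cos(ang) * cc[2]
    i <- min(1 + floor((vc + 1) / 2 * n), n)
    j <- min(1 + floor((wc + 1) / 2 * n), n)
    expect_lt(abs(blobMass(i, j) - 1 / 3), 0.02)  # absolute mass tolerance
  }
})

test_that("symmetrize is idempotent up to resampling tolerance", {
  n <- 128L; B <- 1
  cc <- -B + 2 * B * (seq_len(n) - 0.5) / n
  g <- outer(cc, cc, function(v, w)
    exp(-((v - 0.3)^2 + (w + 0.2)^2) / (2 * 0.15^2)))
  g <- new("DensityGrid", rho = g / sum(g), extent = B, n = n)
  s1 <- symmetrize(g)
  s2 <- symmetrize(s1)
  expect_lt(max(abs(densityMatrix(s2) - densityMatrix(s1))), 1e-5)
})

test_that("attractor size is homogeneous, offset-invariant and calibrated", {
  sig <- idealTrain(amplitude = 40, duration = 20)
  uvw <- pipelineUVW(sig)
  S <- attractorSize(uvw)
  ## calibration recovers the pulse amplitude within 2%
  expect_lt(abs(S - 40), 0.8)
  ## independent amplitude
  expect_lt(abs(attractorSize(pipelineUVW(idealTrain(amplitude = 25,
                                                     duration = 20))) - 25),
            0.5)
  ## exact homogeneity: scaling the points scales the size
  scaled <- uvwFromPoints(3 * uvw@v, 3 * uvw@w)
  expect_equal(attractorSize(scaled), 3 * S, tolerance = 1e-12)
  ## offset invariance through the full pipeline
  shifted <- pulseSignal(samples(sig) + 60, fs = sampleRate(sig))
  expect_equal(attractorSize(pipelineUVW(shifted)), S, tolerance = 1e-9)
  ## degenerate cloud
  expect_identical(attractorSize(uvwFromPoints(rep(1, 200), rep(1, 200))), 0)
})

test_that("rotation angle: calibration zero, exact equivariance, error case", {
  uvw <- pipelineUVW(idealTrain(duration = 20))
  theta <- rotationAngle(density2d(uvw))
  expect_lt(abs(theta), 0.5)
  ## rotating the cloud by +10 degrees adds 10 to the angle
  a <- 10 * pi / 180
  rot <- uvwFromPoints(cos(a) * uvw@v - sin(a) * uvw@w,
                       sin(a) * uvw@v + cos(a) * uvw@w)
  expect_equal(rotationAngle(density2d(rot)) - theta, 10, tolerance = 0.5)
  ## an exactly rotation-symmetric density has no triangular orientation
  n <- 64L
  cc <- -1 + 2 * (seq_len(n) - 0.5) / n
  g <- outer(cc, cc, function(v, w) exp(-(v^2 + w^2) / (2 * 0.3^2)))
  sym <- new("DensityGrid", rho = g / sum(g), extent = 1, n = n)
  expect_error(rotationAngle(sym), "no triangular orientation")
})

test_that("arm widths recover a known transverse spread", {
  set.seed(14)
  sigma <- 0.03
  seg <- function(centreDeg) {
    tt <- runif(3000, -0.5, 0.5)
    ca <- centreDeg * pi / 180
    cbind(0.5 * cos(ca) - tt * sin(ca) + rnorm(3000, 0, sigma),
          0.5 * sin(ca) + tt * cos(ca) + rnorm(3000, 0, sigma))
  }
  pts <- rbind(seg(30), seg(150), seg(-90))  # canonical side directions
  res <- armWidths(uvwFromPoints(pts[, 1], pts[, 2]), theta = 0)
  for (s in 1:3) expect_lt(abs(res$widths[s] - sigma) / sigma, 0.10)
  ## uniform density along each edge: low coefficient of variation
  expect_true(all(res$edgeCV < 0.35))
})

test_that("an exactly periodic waveform has razor-thin arms", {
  uvw <- pipelineUVW(idealTrain(duration = 20))
  S <- attractorSize(uvw)
  res <- armWidths(uvw, rotationAngle(density2d(uvw)))
  expect_true(all(res$widths < 0.01 * S))
})

test_that("sparse sectors are reported as missing, not fabricated", {
  set.seed(15)
  ## points on two sides only (sector 3 nearly empty)
  tt <- runif(2000, -0.5, 0.5)
  v <- c(0.5 * cos(pi / 6) - tt[1:1000] * sin(pi / 6),
         0.5 * cos(5 * pi / 6) - tt[1001:2000] * sin(5 * pi / 6))
  w <- c(0.5 * sin(pi / 6) + tt[1:1000] * cos(pi / 6),
         0.5 * sin(5 * pi / 6) + tt[1001:2000] * cos(5 * pi / 6))
  res <- armWidths(uvwFromPoints(v, w), theta = 0)
  expect_true(is.na(res$widths[3]))
  expect_false(anyNA(res$widths[1:2]))
  expect_error(armWidths(uvwFromPoints(1:100, 1:100), 0), "300")
})

test_that("periodicity score: definition and response to amplitude jitter", {
  expect_identical(periodicityScore(c(0, 0, 0), 5), 0)
  expect_equal(periodicityScore(c(1, 1, 1), 10), 0.1)
  expect_equal(periodicityScore(c(1, NA, 3), 10), 0.2)
  expect_error(periodicityScore(c(1, 1, 1), 0), "positive")
  ## amplitude jitter makes the waveform less periodic (paired, same seed)
  score <- function(sdA) {
    uvw <- pipelineUVW(jitterTrain(sdAmplitude = sdA, duration = 40,
                                   seed = 9L))
    periodicityScore(armWidths(uvw, rotationAngle(density2d(uvw)))$widths,
                     attractorSize(uvw))
  }
  expect_gt(score(0.1), score(0))
})

test_that("u statistics recover level and trend of the raw signal", {
  flatU <- projectUVW(delayEmbed(pulseSignal(rep(7, 300), fs = 100), 0.1))
  us <- uStatistics(flatU)
  expect_equal(us$uMean, 7, tolerance = 1e-12)
  expect_equal(us$uTrend, 0, tolerance = 1e-12)

  ## drifting signal: slope in units per second
  sig <- idealTrain(duration = 20)
  us <- uStatistics(projectUVW(delayEmbed(
    addBaselineWander(sig, driftRate = 1), 1 / 3)))
  expect_equal(us$uTrend, 1, tolerance = 0.01)

  ## periodic train with offset: u mean equals the direct window mean
  ## (fs and duration chosen so the embedding spans whole periods)
  sigO <- generatePulseTrain(pulseParams(period = 1, amplitude = 1,
                                         upstrokeFrac = 0.2, concavity = 1,
                                         offset = 100, seed = 1L),
                             durationS = 2600 / 300, fs = 300)
  uvw <- projectUVW(delayEmbed(sigO, 100 / 300))
  expect_equal(uStatistics(uvw)$uMean, mean(samples(sigO)[201:2600]),
               tolerance = 1e-9)
})

test_that("the full window pipeline returns a coherent feature bundle", {
  f <- windowFeatures(idealTrain(period = 0.8, amplitude = 40, fs = 250,
                                 duration = 10, concavity = 1.5,
                                 offset = 80),
                      featureConfig("human"))
  expect_s4_class(f, "AttractorFeatures")
  expect_equal(f@period, 0.8, tolerance = 1e-3)
  expect_equal(f@hr, 75, tolerance = 0.1)
  expect_gt(f@size, 35)
  expect_lt(f@rotation, 0)       # concave downstroke: clockwise
  expect_equal(f@uMean, mean(samples(idealTrain(period = 0.8, amplitude = 40,
                                                fs = 250, duration = 10,
                                                concavity = 1.5,
                                                offset = 80))),
               tolerance = 0.5)
  df <- as.data.frame(f)
  expect_identical(nrow(df), 1L)
  expect_identical(df$flag, "ok")
})
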