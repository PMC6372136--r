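test_that("stationary records give the predicted window count and stable features", {
  sig <- idealTrain(period = 0.8, amplitude = 40, fs = 250, duration = 60,
                    concavity = 1.5, offset = 80)
  res <- track(sig, windowSpec(10, 5))
  expect_identical(nrow(res), 11L)  # floor((60 - 10)/5) + 1
  expect_true(all(res$flag == "ok"))
  expect_equal(res$window_start_s, seq(0, 50, by = 5))
  cv <- function(x) sd(x) / mean(x)
  for (col in c("T_s", "HR_bpm", "size", "u_mean"))
    expect_lt(abs(cv(res[[col]])), 0.02)
  ## width-derived features sit on the small arm-curvature floor (~1% of
  ## size for this concavity), so per-window cycle-estimate wiggle moves
  ## them relatively more; they must still be tightly stable
  for (col in c("arm1_width", "arm2_width", "arm3_width", "periodicity"))
    expect_lt(abs(cv(res[[col]])), 0.05)
  expect_lt(max(res$rotation_deg) - min(res$rotation_deg), 0.5)
})

test_that("a pulse-pressure step doubles the tracked attractor size", {
  a <- idealTrain(period = 0.8, amplitude = 20, fs = 250, duration = 30,
                  concavity = 1.5, offset = 80, seed = 4L)
  b <- idealTrain(period = 0.8, amplitude = 40, fs = 250, duration = 30,
                  concavity = 1.5, offset = 80, seed = 4L)
  sig <- pulseSignal(c(samples(a), samples(b)), fs = 250)
  res <- track(sig, windowSpec(10, 10))
  expect_identical(nrow(res), 6L)
  expect_equal(res$size[6] / res$size[1], 2, tolerance = 0.05)
})

test_that("masking: windows per segment follow the formula, nothing dropped", {
  sig <- idealTrain(period = 0.8, amplitude = 40, fs = 250, duration = 60,
                    concavity = 1.5)
  mask <- artifactMask(25, 28)
  res <- track(sig, windowSpec(10, 5), mask = mask)
  ## segments of 25 s and 32 s: floor((25-10)/5)+1 + floor((32-10)/5)+1
  expect_identical(nrow(res), 4L + 5L)
  expect_true(all(res$window_end_s <= 25 | res$window_start_s >= 28))
  ## failure flags count as rows, never silent drops
  expect_identical(nrow(res), sum(res$flag == "ok") + sum(res$flag != "ok"))

  expect_error(track(sig, windowSpec(10, 5), mask = artifactMask(0, 60)),
               "whole signal")
  expect_error(track(sig, windowSpec(50, 5), mask = artifactMask(25, 28)),
               "longer than every")
})

test_that("windows that defeat cycle estimation are flagged, not dropped", {
  good <- idealTrain(period = 0.8, amplitude = 40, fs = 250, duration = 20,
                     concavity = 1.5)
  flat <- pulseSignal(rep(80, 250 * 10), fs = 250)
  sig <- pulseSignal(c(samples(good), samples(flat)), fs = 250)
  res <- track(sig, windowSpec(10, 10))
  expect_identical(nrow(res), 3L)
  expect_identical(sum(res$flag == "ok"), 2L)
  expect_match(res$flag[3], "periodicity")
  expect_true(is.na(res$size[3]))
})

test_that("the CLI round-trips synth -> track deterministically", {
  dir <- withr::local_tempdir()
  scsv <- file.path(dir, "s.csv")
  code <- suppressMessages(pulseCLI(c("synth", "--out", scsv, "--duration", "60",
                     "--fs", "250", "--period", "0.8", "--seed", "7")))
  expect_identical(code, 0L)
  expect_true(file.exists(scsv))
  expect_true(file.exists(paste0(scsv, ".json")))

  f1 <- file.path(dir, "f1.csv"); f2 <- file.path(dir, "f2.csv")
  expect_identical(suppressMessages(
    pulseCLI(c("track", "--input", scsv, "--out", f1,
               "--window", "10", "--step", "5"))), 0L)
  expect_identical(suppressMessages(
    pulseCLI(c("track", "--input", scsv, "--out", f2,
               "--window", "10", "--step", "5"))), 0L)
  expect_identical(readLines(f1), readLines(f2))
  res <- read.csv(f1)
  expect_identical(nrow(res), 11L)
  expect_true(file.exists(paste0(f1, ".config.json")))

  ## value-only input without --fs is an input error (exit 2)
  vcsv <- file.path(dir, "v.csv")
  writeLines(sprintf("%.6f", samples(readSignal(scsv))[1:5000]), vcsv)
  expect_identical(
    suppressMessages(pulseCLI(c("track", "--input", vcsv,
                                "--out", file.path(dir, "x.csv")))), 2L)
  ## unknown flags are input errors too
  expect_identical(
    suppressMessages(pulseCLI(c("track", "--input", scsv, "--out", f1,
                                "--bogus", "1"))), 2L)
  expect_identical(suppressMessages(pulseCLI(c("nonsense"))), 2L)
})

test_that("the attractor subcommand exports a normalized density", {
  dir <- withr::local_tempdir()
  scsv <- file.path(dir, "s.csv")
  suppressMessages(pulseCLI(c("synth", "--out", scsv, "--duration", "12",
                              "--fs", "250", "--period", "0.8")))
  dout <- file.path(dir, "d.txt")
  expect_identical(suppressMessages(
    pulseCLI(c("attractor", "--input", scsv, "--out", dout,
               "--n", "64"))), 0L)
  m <- as.matrix(read.table(dout))
  expect_identical(dim(m), c(64L, 64L))
  expect_lt(abs(sum(m) - 1), 1e-9)
  meta <- jsonlite::read_json(paste0(dout, ".json"))
  expect_gt(meta$extent, 0)
})
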