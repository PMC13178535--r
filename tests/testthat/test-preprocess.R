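test_that("oxyhaemoglobin index is the TOI x nTHI product", {
  expect_identical(compute_o2hb_srs(68, 1.00), 68)
  expect_equal(compute_o2hb_srs(66, 1.06), 69.96)
  toi <- c(61.2, 70.5, 68.3)
  expect_identical(compute_o2hb_srs(toi, rep(1, 3)), toi)
  expect_error(compute_o2hb_srs(c(68, 68), 1), "length")
  expect_error(compute_o2hb_srs(68, -0.1), "> 0")
  expect_error(compute_o2hb_srs(120, 1), "100")
})

test_that("beat averaging matches closed forms and a dense-grid oracle", {
  fs <- 100
  # constant signal: every beat equals the constant
  x <- rep(90, 10 * fs + 1)
  rp <- c(0.31, 1.12, 1.95, 2.83, 3.64, 9.2)
  ba <- beat_average(x, fs, rp)
  expect_equal(ba$values, rep(90, 5), tolerance = 1e-12)
  expect_identical(ba$beat_times, rp[-6])

  # linear ramp 0 -> 1 over one beat: interval time-average is 1/2
  tt <- seq(0, 1, by = 1 / fs)
  ba <- beat_average(tt, fs, c(0, 1))
  expect_equal(ba$values, 0.5, tolerance = 1e-12)

  # full-cycle sinusoid averages to ~0; fractional beats match the oracle
  f0 <- 1
  tt <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * f0 * tt)
  ba <- beat_average(x, fs, 0:5)
  expect_lt(max(abs(ba$values)), 1e-10)

  set.seed(4)
  rp <- sort(runif(8, 0.2, 19.5))
  ba <- beat_average(x, fs, rp)
  oracle <- vapply(seq_len(7), function(k) {
    dense_interval_mean(function(t) sin(2 * pi * f0 * t), rp[k], rp[k + 1])
  }, numeric(1))
  # both integrate the same linear interpolant up to O(h^2) discretisation
  expect_equal(ba$values, oracle, tolerance = 1e-3)

  expect_error(beat_average(x, fs, c(0, 25)), "support")
  expect_error(beat_average(x, fs, c(1, 1)), "interval")
  expect_error(beat_average(x, fs, 1), "2 R-peaks")
})

test_that("R-peak detection recovers simulator ground truth", {
  sub <- quick_subject(seed = 31)
  ecg <- sub$recording$channels$ECG
  truth <- sub$truth$rpeak_times
  det <- detect_rpeaks(ecg$values, ecg$fs)
  expect_equal(length(det), length(truth))
  expect_lt(max(abs(det - truth)), 1 / ecg$fs + 1e-9)

  expect_error(detect_rpeaks(rep(0, 1000), 250), "flat")
  expect_error(detect_rpeaks(rep(1, 1000), 250), "flat")
  expect_error(detect_rpeaks(rnorm(1000), 50), "100 Hz")
})

test_that("provided R-peak times bypass ECG detection", {
  sub <- quick_subject(seed = 32)
  rec <- sub$recording
  # corrupt the ECG: preprocessing must still use the supplied times
  rec$channels$ECG$values <- rec$channels$ECG$values * 0
  pp <- preprocess_recording(rec)
  expect_identical(pp$rpeak_times, rec$rpeak_times)
})

test_that("percent-of-mean normalisation has its closed forms", {
  expect_equal(normalize_percent(c(50, 60, 70)),
               c(250 / 3, 100, 350 / 3), tolerance = 1e-12)
  expect_identical(normalize_percent(rep(7, 5)), rep(100, 5))
  expect_error(normalize_percent(c(-1, 1)), "zero-mean")
})

test_that("resampling is linear interpolation onto a 2 Hz grid", {
  # beats already on the grid: passthrough
  bt <- seq(0, 10, by = 0.5)
  v <- rnorm(length(bt))
  us <- resample_uniform(v, bt)
  expect_equal(us$values, v, tolerance = 1e-12)
  expect_identical(us$fs, 2)

  # two beats: closed-form midpoint
  us <- resample_uniform(c(0, 1), c(0, 1))
  expect_equal(us$values, c(0, 0.5, 1), tolerance = 1e-12)

  # known curvature: linear-interpolation error bound h^2 max|f''| / 8
  set.seed(9)
  bt <- sort(c(0, runif(200, 0, 30), 30))
  f <- function(t) sin(2 * pi * 0.1 * t)
  us <- resample_uniform(f(bt), bt)
  grid <- us$t0 + (seq_along(us$values) - 1) / us$fs
  h <- max(diff(bt))
  bound <- h^2 * (2 * pi * 0.1)^2 / 8
  expect_lt(max(abs(us$values - f(grid))), bound + 1e-12)

  # interior NaN gaps are bridged linearly before interpolation
  v <- c(0, NaN, NaN, 3, 4)
  us <- resample_uniform(v, 0:4, fs = 1)
  expect_equal(us$values, c(0, 1, 2, 3, 4), tolerance = 1e-12)

  expect_error(resample_uniform(1, 1), "2 beats")
})

test_that("cubic detrending annihilates cubics and is idempotent", {
  tt <- seq_len(400)
  cubic <- 2 + 0.01 * tt - 3e-5 * tt^2 + 5e-8 * tt^3
  out <- detrend_poly(cubic)
  expect_lt(max(abs(out)), 1e-9 * sd(cubic))

  wave <- sin(2 * pi * 0.05 * tt)
  out <- detrend_poly(cubic + wave)
  # the sinusoid survives detrending up to its own small cubic projection
  expect_equal(out, detrend_poly(wave), tolerance = 1e-9)
  expect_lt(abs(mean(out)), 1e-9 * sd(cubic + wave))

  expect_identical(detrend_poly(rep(0, 50)), rep(0, 50))
  twice <- detrend_poly(out)
  expect_equal(twice, out, tolerance = 1e-9)
  expect_error(detrend_poly(1:4, order = 3), "short")
})

test_that("preprocessing pipeline satisfies its stage contracts", {
  sub <- quick_subject(seed = 33, duration_s = 120)
  pp <- preprocess_recording(sub$recording)

  b <- pp$beats
  # product invariant at beat level, machine precision
  expect_equal(b$o2hb, b$toi * b$nthi, tolerance = 1e-15)
  # hr consistent with R-R intervals
  expect_equal(b$hr, 60 / diff(pp$rpeak_times), tolerance = 1e-12)
  expect_true(all(diff(b$beat_time) > 0))

  for (nm in c("map", "cbfv", "o2hb")) {
    us <- pp$series[[nm]]
    expect_s3_class(us, "uniform_series")
    expect_identical(us$fs, 2)
    expect_true(us$detrended)
    expect_false(anyNA(us$values))
    expect_lt(abs(mean(us$values)), 1e-9 * (sd(us$values) + 1e-300))
  }
  expect_identical(pp$series$map$units, "mmHg")
  expect_identical(pp$series$cbfv$units, "percent_of_mean")

  # percent normalisation: beat-level mean is exactly 100
  expect_equal(mean(normalize_percent(b$cbfv)), 100, tolerance = 1e-12)
})
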