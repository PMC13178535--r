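test_that("the standard settings give the printed 0.0078 Hz resolution", {
  set.seed(1)
  s <- welch_spectra(rnorm(600), rnorm(600), fs = 2, nperseg = 256)
  expect_equal(unique(round(diff(s$freqs), 12)), 0.0078125)
  expect_identical(sprintf("%.4f", diff(s$freqs)[1]), "0.0078")
  expect_identical(s$freqs[1], 0)
  expect_equal(s$n_segments, floor((600 - 256) / 128) + 1)
})

test_that("Welch estimates match a naive periodogram oracle", {
  set.seed(2)
  n <- 64
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  s <- welch_spectra(x, y, fs = 2, nperseg = n)   # single segment
  o <- naive_cross_periodogram(x, y, fs = 2)
  expect_equal(s$freqs, o$freqs, tolerance = 1e-12)
  expect_equal(s$Sxx, o$Sxx, tolerance = 1e-10)
  expect_equal(s$Sxy, o$Sxy, tolerance = 1e-10)
})

test_that("self-coherence is one and auto-spectra are non-negative", {
  set.seed(3)
  x <- rnorm(700)
  s <- welch_spectra(x, x)
  msc <- Mod(s$Sxy)^2 / (s$Sxx * s$Syy)
  expect_equal(msc, rep(1, length(msc)), tolerance = 1e-12)
  expect_true(all(s$Sxx >= 0))
})

test_that("white-noise PSD is flat at variance / bandwidth (Parseval)", {
  set.seed(4)
  x <- rnorm(4096)
  p <- psd(x, fs = 2)
  # unit variance spread over 1 Hz of one-sided bandwidth
  expect_equal(mean(p$psd), 1, tolerance = 0.05)
  band_power <- sum(p$psd) * (p$freq[2] - p$freq[1])
  expect_equal(band_power, var(x), tolerance = 0.05)

  expect_identical(psd(rep(0, 600))$psd, rep(0, 129))

  # a pure 0.05 Hz tone concentrates power in the two flanking bins
  tt <- (0:599) / 2
  p <- psd(sin(2 * pi * 0.05 * tt), fs = 2)
  top2 <- order(p$psd, decreasing = TRUE)[1:2]
  expect_setequal(p$freq[top2], c(0.046875, 0.0546875))
  expect_gt(sum(p$psd[top2]) / sum(p$psd), 0.8)
})

test_that("transfer function recovers scaling, delay and phase sign", {
  set.seed(5)
  x <- rnorm(1024)
  s <- welch_spectra(x, 2 * x)
  tf <- transfer_function(s)
  sel <- tf$freqs > 0
  expect_equal(tf$gain[sel], rep(2, sum(sel)), tolerance = 1e-10)
  expect_equal(tf$phase[sel], rep(0, sum(sel)), tolerance = 1e-10)
  expect_equal(tf$coherence[sel], rep(1, sum(sel)), tolerance = 1e-10)

  # delay of tau = 1.5 s at fs = 2: output lags, phase slope = -2 pi tau
  # (windowed segments see the shift only approximately, so a few percent
  # of leakage scatter remains around the exact delay line)
  tau <- 1.5
  y <- c(tail(x, 3), head(x, -3))
  tf <- transfer_function(welch_spectra(x, y))
  sel <- tf$freqs > 0 & tf$freqs < 0.3
  expect_equal(tf$gain[sel], rep(1, sum(sel)), tolerance = 0.05)
  expect_equal(wrap_diff(tf$phase[sel] - (-2 * pi * tf$freqs[sel] * tau)),
               rep(0, sum(sel)), tolerance = 0.05)
  slope <- coef(lm(tf$phase[sel] ~ 0 + tf$freqs[sel]))
  expect_equal(unname(slope), -2 * pi * tau, tolerance = 0.01)
  # output leading the input gives positive phase
  tf <- transfer_function(welch_spectra(y, x))
  expect_true(all(tf$phase[sel] > 0))

  # invariance to common positive scaling
  s1 <- transfer_function(welch_spectra(x, y))
  s2 <- transfer_function(welch_spectra(5 * x, 5 * y))
  expect_equal(s1$gain, s2$gain, tolerance = 1e-12)
  expect_equal(s1$coherence, s2$coherence, tolerance = 1e-12)
})

test_that("coherence respects the Cauchy-Schwarz bound on random inputs", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(300:900, 1)
    x <- cumsum(rnorm(n))            # correlated, non-white
    y <- 0.5 * x + cumsum(rnorm(n))
    x <- detrend_poly(x); y <- detrend_poly(y)
    s <- welch_spectra(x, y)
    expect_true(all(Mod(s$Sxy)^2 <= s$Sxx * s$Syy * (1 + 1e-12)))
    tf <- transfer_function(s)
    ok <- tf$valid
    expect_true(all(tf$coherence[ok] >= 0 & tf$coherence[ok] <= 1 + 1e-12))
    expect_true(all(tf$phase[ok] > -pi - 1e-12 & tf$phase[ok] <= pi + 1e-12))
    expect_equal(tf$gain[ok], Mod(tf$H[ok]), tolerance = 1e-15)
  }
})

test_that("noiseless simulated stage matches its analytic response closely", {
  # long record, spectrally flat drive: isolates estimator fidelity
  sub <- simulate_subject(sim_config(condition = "rest", seed = 3,
                                     duration_s = 1800,
                                     rest_drive_alpha = 0))
  pp <- preprocess_recording(sub$recording)
  spec <- cascade_spectra(pp$series$map, pp$series$cbfv, pp$series$o2hb)
  h1 <- transfer_function(spec, pathway = "H1")
  truth <- sub$truth$H1
  sel <- which(h1$freqs >= 0.02 & h1$freqs <= 0.35 & h1$coherence > 0.9)
  expect_gt(length(sel), 30)
  expect_lt(max(abs(h1$gain[sel] - Mod(truth[sel])) / Mod(truth[sel])), 0.05)
  expect_lt(max(abs(wrap_diff(h1$phase[sel] - Arg(truth[sel])))), 0.05)
  # the autoregulatory high-pass renders positive phase in VLF/LF
  vlf_lf <- h1$freqs >= 0.02 & h1$freqs < 0.20
  expect_true(all(h1$phase[vlf_lf] > 0))
})

test_that("degenerate spectral inputs error or are flagged", {
  expect_error(welch_spectra(rnorm(100), rnorm(100)), "shorter")
  expect_error(welch_spectra(rnorm(300), rnorm(299)), "equal length")
  # zero input power: bins marked invalid, not infinite
  s <- welch_spectra(rep(0, 600), rnorm(600))
  tf <- transfer_function(s)
  expect_true(all(!tf$valid))
  expect_true(all(is.na(tf$gain)))
})
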