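test_that("cascade combination multiplies gains, adds phases, multiplies coherences", {
  freqs <- (0:128) * 2 / 256
  # group-mean worked example at 0.05 Hz during forced oscillations
  h1 <- make_tf(freqs, gain = 1.64, phase = 0.85, coherence = 0.95, "H1")
  h2 <- make_tf(freqs, gain = 0.20, phase = -1.07, coherence = 0.91, "H2")
  hc <- cascade_combine(h1, h2)
  expect_equal(hc$gain, rep(0.328, 129), tolerance = 1e-12)
  expect_equal(hc$phase, rep(-0.22, 129), tolerance = 1e-12)
  expect_equal(hc$coherence, rep(0.95 * 0.91, 129), tolerance = 1e-12)
  # complex product consistent with the per-index arithmetic
  expect_equal(Mod(hc$H), hc$gain, tolerance = 1e-12)
  expect_equal(Arg(hc$H), hc$phase, tolerance = 1e-12)

  # identity downstream stage leaves the upstream result unchanged
  ident <- make_tf(freqs, 1, 0, 1, "H2")
  hc <- cascade_combine(h1, ident)
  expect_equal(hc$gain, h1$gain, tolerance = 1e-15)
  expect_equal(hc$phase, h1$phase, tolerance = 1e-15)
  expect_equal(hc$coherence, h1$coherence, tolerance = 1e-15)

  # phase sums re-wrap into (-pi, pi]
  ha <- make_tf(freqs, 1, 2.5, 1)
  hb <- make_tf(freqs, 1, 2.0, 1, "H2")
  hc <- cascade_combine(ha, hb)
  expect_equal(hc$phase, rep(4.5 - 2 * pi, 129), tolerance = 1e-12)
  expect_equal(hc$phase, Arg(ha$H * hb$H), tolerance = 1e-12)

  expect_error(cascade_combine(ha, make_tf(freqs[-1], 1, 0, 1)), "grid")
})

test_that("cascade coherence never exceeds either component", {
  set.seed(7)
  for (i in 1:10) {
    p <- detrend_poly(cumsum(rnorm(800)))
    v <- 0.7 * p + rnorm(800)
    c_ <- 0.5 * v + rnorm(800)
    spec <- cascade_spectra(p, v, c_)
    hc <- cascade_combine(transfer_function(spec, pathway = "H1"),
                          transfer_function(spec, pathway = "H2"))
    ok <- hc$valid
    expect_true(all(hc$coherence[ok] <=
                      pmin(hc$h1$coherence[ok], hc$h2$coherence[ok]) + 1e-12))
    expect_true(all(hc$coherence[ok] <= 1 + 1e-12))
  }
})

test_that("the two bins flanking 0.05 Hz are 0.046875 and 0.0546875 Hz", {
  freqs <- (0:128) * 2 / 256
  bins <- cascadeTFA:::f005_bins(freqs)
  expect_equal(freqs[bins], c(0.046875, 0.0546875))
  expect_equal(bins, c(7L, 8L))  # 1-based; bins 6 and 7 of the FFT grid
})

test_that("band summaries average the right bins", {
  freqs <- (0:128) * 2 / 256
  tf <- make_tf(freqs, gain = 3.5, phase = 0.2, coherence = 0.5)
  bs <- band_summary(tf, "rest")
  expect_identical(bs$band, c("VLF", "LF", "HF"))
  expect_equal(bs$gain, rep(3.5, 3), tolerance = 1e-15)
  # left-closed right-open edges on the default grid
  expect_equal(bs$n_bins, c(6L, 17L, 19L))

  # linear ramp across the VLF bins averages to the midpoint value
  ramp <- make_tf(freqs, gain = freqs, phase = 0, coherence = 1)
  bs <- band_summary(ramp, "rest")
  vlf_bins <- which(freqs >= 0.02 & freqs < 0.07)
  expect_equal(bs$gain[1], (freqs[vlf_bins[1]] + freqs[vlf_bins[6]]) / 2,
               tolerance = 1e-15)

  # sit-stand: exactly the two flanking bins
  bs <- band_summary(tf, "sit_stand")
  expect_identical(bs$band, "F005")
  expect_identical(bs$n_bins, 2L)

  # a band with no valid bins is undefined, not zero
  tf$valid[freqs >= 0.20 & freqs < 0.35] <- FALSE
  bs <- band_summary(tf, "rest")
  expect_true(is.na(bs$gain[bs$band == "HF"]))
  expect_identical(bs$n_bins[bs$band == "HF"], 0L)
})

test_that("negative low-frequency phases at rest are excluded from phase means", {
  freqs <- (0:128) * 2 / 256
  phase <- rep(0.5, 129)
  phase[freqs > 0.04 & freqs < 0.06] <- -0.3   # wrapped bins near 0.05 Hz
  tf <- make_tf(freqs, 1.5, phase, 0.9)

  keep <- phase_exclusion_mask(tf, "rest")
  expect_true(all(!keep[freqs > 0.04 & freqs < 0.06]))
  expect_true(all(keep[freqs >= 0.10]))

  bs <- band_summary(tf, "rest", phase_keep = keep)
  expect_equal(bs$phase[bs$band == "VLF"], 0.5, tolerance = 1e-15)
  expect_lt(bs$n_phase_bins[1], bs$n_bins[1])
  # gain and coherence means keep all bins
  expect_equal(bs$gain[1], 1.5, tolerance = 1e-15)

  # all-positive phases: mask is all-true, means unchanged
  tf2 <- make_tf(freqs, 1.5, 0.5, 0.9)
  expect_true(all(phase_exclusion_mask(tf2, "rest")))
  # rule is scoped to rest
  expect_true(all(phase_exclusion_mask(tf, "sit_stand")))
})

test_that("significant coupling uses a strict threshold", {
  expect_true(coupling_significance(0.95))
  expect_false(coupling_significance(0.34))   # boundary: strict inequality
  expect_false(coupling_significance(0.2))
  expect_true(is.na(coupling_significance(NA_real_)))

  # all 36 sit-stand subjects above threshold -> 36 (100%)
  res <- data.frame(subject_id = sprintf("S%02d", 1:36), pathway = "H1",
                    band = "F005", coherence = runif(36, 0.5, 1))
  counts <- cohort_coupling_counts(res)
  expect_identical(counts$n_significant, 36L)
  expect_identical(counts$n_total, 36L)
  expect_equal(counts$percent, 100)

  res$coherence[3] <- NA
  expect_message(counts <- cohort_coupling_counts(res), "undefined")
  expect_identical(counts$n_total, 35L)
})

test_that("Monte Carlo critical coherence behaves consistently", {
  cv5 <- coherence_critical_value(5, n_sim = 1500, seed = 42)
  expect_equal(cv5, 0.34, tolerance = 0.05)
  cv2 <- coherence_critical_value(2, n_sim = 1500, seed = 42)
  expect_gt(cv2, cv5)   # fewer windows, higher threshold
  # more averaging drives the null coherence down
  cv12 <- coherence_critical_value(12, n_sim = 1500, seed = 42)
  expect_lt(cv12, cv5)
  expect_warning(coherence_critical_value(5, n_sim = 500, seed = 1), "noisy")
  # deterministic given the seed
  expect_identical(cv5, coherence_critical_value(5, n_sim = 1500, seed = 42))
})
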