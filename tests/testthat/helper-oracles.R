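# Independent oracles and small fixtures used across test files.

# wrap angle differences to (-pi, pi]
wrap_diff <- function(p) {
  out <- (p + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# dense-grid numerical time-average of f over [a, b): independent of the
# package's trapezoid-with-fractional-endpoints implementation
dense_interval_mean <- function(f, a, b, n = 20001) {
  tt <- seq(a, b, length.out = n)
  h <- tt[2] - tt[1]
  y <- f(tt)
  sum((y[-1] + y[-n]) / 2 * h) / (b - a)
}

# naive single-segment cross-periodogram written with explicit sums, as an
# independent check of the Welch estimator's conventions and scaling
naive_cross_periodogram <- function(x, y, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  xw <- x * w
  yw <- y * w
  nb <- n %/% 2 + 1
  freqs <- (0:(nb - 1)) * fs / n
  X <- Y <- complex(nb)
  for (k in 0:(nb - 1)) {
    e <- exp(-2i * pi * k * (0:(n - 1)) / n)
    X[k + 1] <- sum(xw * e)
    Y[k + 1] <- sum(yw * e)
  }
  scale <- 2 / (fs * sum(w^2))
  scale_vec <- rep(scale, nb)
  scale_vec[c(1, nb)] <- scale / 2
  list(freqs = freqs, Sxx = Mod(X)^2 * scale_vec,
       Sxy = Conj(X) * Y * scale_vec)
}

# build a minimal tf_result by hand (for cascade arithmetic tests)
make_tf <- function(freqs, gain, phase, coherence, pathway = "H1") {
  gain <- rep_len(gain, length(freqs))
  phase <- rep_len(phase, length(freqs))
  coherence <- rep_len(coherence, length(freqs))
  structure(list(freqs = freqs, H = gain * exp(1i * phase), gain = gain,
                 phase = phase, coherence = coherence,
                 valid = rep(TRUE, length(freqs)), pathway = pathway,
                 gain_units = "", n_segments = 5),
            class = "tf_result")
}

# short simulated subject shared by IO / preprocessing tests
quick_subject <- function(seed = 5, condition = "rest", duration_s = 60,
                          ...) {
  simulate_subject(sim_config(condition = condition, duration_s = duration_s,
                              seed = seed, ...))
}
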