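#' Configuration for the synthetic cerebrovascular signal simulator
#'
#' Defines a ground-truth series (cascade) linear system driven by an
#' arterial-pressure input. Stage 1 (pressure -> flow velocity) is a stable
#' high-pass filter, giving the positive low-frequency phase lead
#' characteristic of dynamic cerebral autoregulation; stage 2 (flow velocity
#' -> oxyhaemoglobin) is a low-pass filter plus a pure transport delay,
#' giving strong attenuation and negative phase as seen in cortical
#' microvascular responses. Independent band-limited disturbances can be
#' injected after each stage. Default means follow healthy young adults
#' (MAP 91 mmHg / HR 69 bpm at rest; 100 mmHg / 83 bpm during the sit-stand
#' manoeuvre); default stage gains sit in the observed ranges (~1.5 %/mmHg
#' upstream, ~0.18 %/% downstream).
#'
#' @param condition `"rest"` (spontaneous broadband pressure fluctuations) or
#'   `"sit_stand"` (dominant 0.05 Hz forced oscillation from 10 s sit /
#'   10 s stand cycles).
#' @param duration_s recording length (default 300 s).
#' @param seed integer; fully determines the output.
#' @param map_mean,hr_mean,cbfv_mean,toi_mean,nthi_mean channel means;
#'   `NULL` picks the condition-specific default.
#' @param g1 stage-1 gain at the 0.05 Hz reference frequency (%/mmHg).
#' @param f1_corner stage-1 high-pass corner frequency (Hz).
#' @param stage1_order stage-1 filter order (1 or 2).
#' @param g2 stage-2 static (DC) gain (%/%).
#' @param f2_corner stage-2 low-pass corner frequency (Hz).
#' @param delay_s stage-2 pure delay (s).
#' @param noise_cbfv_sd,noise_o2hb_sd SD of the independent additive
#'   disturbances (in % of mean) entering at the flow-velocity and
#'   oxyhaemoglobin stages (defaults 0, for identity testing).
#' @param forcing_amp peak-to-trough amplitude of the sit-stand pressure
#'   square wave (mmHg, default 15).
#' @param forcing_period sit-stand cycle length (s, default 20, i.e.
#'   0.05 Hz).
#' @param rest_drive_sd SD of the band-limited (0.01-0.40 Hz) 1/f-like
#'   spontaneous pressure drive (mmHg).
#' @param rest_drive_alpha spectral slope of the spontaneous drive
#'   (amplitude ~ f^(-alpha/2); default 1 gives the 1/f-like power spectrum
#'   of resting arterial pressure, 0 gives a flat spectrum useful for
#'   estimator-fidelity checks free of leakage bias).
#' @param nthi_fluct_sd SD of the slow nTHI fluctuation (a.u., default 0.02;
#'   TOI is synthesised as the oxyhaemoglobin target divided by nTHI so
#'   their product carries the oxygenation signal exactly).
#' @param include_ecg synthesise an ECG channel (impulse-like template at
#'   each R-peak)?
#' @return A `sim_config` list.
#' @export
sim_config <- function(condition = c("rest", "sit_stand"),
                       duration_s = 300, seed = 1,
                       map_mean = NULL, hr_mean = NULL, cbfv_mean = NULL,
                       toi_mean = NULL, nthi_mean = NULL,
                       g1 = 1.5, f1_corner = 0.07, stage1_order = 1,
                       g2 = 0.18, f2_corner = 0.15, delay_s = 1.5,
                       noise_cbfv_sd = 0, noise_o2hb_sd = 0,
                       forcing_amp = 15, forcing_period = 20,
                       rest_drive_sd = 3, rest_drive_alpha = 1,
                       nthi_fluct_sd = 0.02,
                       include_ecg = TRUE) {
  condition <- match.arg(condition)
  ss <- condition == "sit_stand"
  cfg <- list(
    condition = condition, duration_s = duration_s, seed = as.integer(seed),
    map_mean = map_mean %||% if (ss) 100 else 91,
    hr_mean = hr_mean %||% if (ss) 83 else 69,
    cbfv_mean = cbfv_mean %||% if (ss) 54 else 60,
    toi_mean = toi_mean %||% if (ss) 66 else 68,
    nthi_mean = nthi_mean %||% if (ss) 1.06 else 1.00,
    g1 = g1, f1_corner = f1_corner, stage1_order = stage1_order,
    g2 = g2, f2_corner = f2_corner, delay_s = delay_s,
    noise_cbfv_sd = noise_cbfv_sd, noise_o2hb_sd = noise_o2hb_sd,
    forcing_amp = forcing_amp, forcing_period = forcing_period,
    rest_drive_sd = rest_drive_sd, rest_drive_alpha = rest_drive_alpha,
    nthi_fluct_sd = nthi_fluct_sd,
    include_ecg = include_ecg)
  stopifnot(cfg$duration_s > 0, cfg$hr_mean > 0, cfg$map_mean > 0,
            cfg$f1_corner > 0, cfg$f2_corner > 0, cfg$delay_s >= 0,
            cfg$stage1_order %in% 1:2)
  class(cfg) <- "sim_config"
  cfg
}

#' Analytic stage frequency responses
#'
#' Evaluates the simulator's ground-truth transfer functions on an arbitrary
#' frequency grid (negative frequencies allowed; responses are Hermitian).
#' Stage 1: `g1 * B(i f/fc)^order / |B(i 0.05/fc)|^order` with
#' `B(s) = s/(1+s)` - a high-pass normalised so the gain at 0.05 Hz equals
#' `g1`, with phase `order * atan(fc/f) > 0`. Stage 2:
#' `g2 / (1 + i f/fc) * exp(-2i pi f delay)` - low-pass of DC gain `g2`
#' with a pure delay, phase `-atan(f/fc) - 2 pi f delay < 0`.
#'
#' @param cfg a `sim_config`.
#' @param freqs frequency grid in Hz.
#' @return List with complex vectors `H1`, `H2`, and `H0 = H1 * H2`.
#' @export
stage_responses <- function(cfg, freqs) {
  bp <- function(f, fc) {
    s <- 1i * f / fc
    s / (1 + s)
  }
  ref <- Mod(bp(0.05, cfg$f1_corner))^cfg$stage1_order
  H1 <- cfg$g1 * bp(freqs, cfg$f1_corner)^cfg$stage1_order / ref
  H2 <- cfg$g2 / (1 + 1i * freqs / cfg$f2_corner) *
    exp(-2i * pi * freqs * cfg$delay_s)
  list(H1 = H1, H2 = H2, H0 = H1 * H2)
}

# band-limited noise synthesised in the frequency domain on an N-point grid
# at rate fs: amplitude ~ f^(-alpha/2) inside [f_lo, f_hi], random phases,
# scaled to unit SD (returns zeros if the band holds no bins)
band_noise <- function(n, fs, f_lo = 0.01, f_hi = 0.40, alpha = 1) {
  f <- fftfreq(n, fs)
  amp <- rep(0, n)
  sel <- abs(f) >= f_lo & abs(f) <= f_hi
  amp[sel] <- abs(f[sel])^(-alpha / 2)
  ph <- stats::runif(n, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  x <- Re(stats::fft(hermitianize(spec, f), inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s
}

fftfreq <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# impose Hermitian symmetry so the inverse FFT is real
hermitianize <- function(spec, f) {
  n <- length(spec)
  out <- spec
  pos <- which(f > 0)
  neg <- (n - pos + 2)
  ok <- neg >= 1 & neg <= n
  out[neg[ok]] <- Conj(spec[pos[ok]])
  out[f == 0] <- Re(spec[f == 0])
  if (n %% 2 == 0) out[n / 2 + 1] <- Re(spec[n / 2 + 1])
  out
}

# apply an analytic frequency response by circular FFT filtering
apply_response <- function(x, fs, response_fun) {
  n <- length(x)
  H <- response_fun(fftfreq(n, fs))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# zero-mean cardiac pulse shape as a function of beat phase u in [0,1)
pulse_shape <- function(u) {
  (cos(2 * pi * u) + 0.4 * cos(4 * pi * u + 0.8)) / 1.4
}

#' Simulate one subject's multichannel recording
#'
#' Generates a pressure drive (spontaneous 1/f-band noise at rest, a
#' smoothed 0.05 Hz square wave plus residual noise during sit-stand),
#' passes it through the ground-truth cascade (flow velocity =
#' stage1(pressure deviation) + disturbance; oxyhaemoglobin =
#' stage2(flow-velocity deviation) + disturbance - the first-stage
#' disturbance propagates through stage 2, so the population coherence of
#' the total pathway equals the product of the stage coherences), and
#' synthesises the recorded channels: pulsatile arterial pressure (250 Hz),
#' pulsatile CBFV (100 Hz), NIRS TOI and nTHI (5 Hz) whose product
#' reproduces the intended oxyhaemoglobin index exactly, optional ECG
#' (250 Hz), and R-peak times from an integrate-and-fire heart-rate process.
#'
#' @param cfg a `sim_config`.
#' @return List with `recording` (a [recording()]) and `truth` (analytic
#'   `H1`, `H2`, `H0` on the analysis bin grid, the exact R-peak times, and
#'   the configuration).
#' @export
simulate_subject <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  fs <- 500                       # internal grid; channel rates divide it
  n <- round(cfg$duration_s * fs)
  tt <- (0:(n - 1)) / fs

  # --- pressure drive (mmHg deviations around the mean) ---
  map_dev <- cfg$rest_drive_sd *
    band_noise(n, fs, alpha = cfg$rest_drive_alpha)
  if (cfg$condition == "sit_stand") {
    sq <- sign(sin(2 * pi * tt / cfg$forcing_period))
    sq[sq == 0] <- 1
    smooth <- function(f) exp(-0.5 * (2 * pi * f * 1.0)^2)  # 1 s Gaussian
    sq <- apply_response(sq, fs, smooth)
    map_dev <- cfg$forcing_amp / 2 * sq + 0.5 * map_dev
  }

  # --- cascade stages (percent deviations) ---
  resp <- function(which) function(f) stage_responses(cfg, f)[[which]]
  v_pct <- apply_response(map_dev, fs, resp("H1"))
  if (cfg$noise_cbfv_sd > 0)
    v_pct <- v_pct + cfg$noise_cbfv_sd * band_noise(n, fs, 0.01, 0.45)
  c_pct <- apply_response(v_pct, fs, resp("H2"))
  if (cfg$noise_o2hb_sd > 0)
    c_pct <- c_pct + cfg$noise_o2hb_sd * band_noise(n, fs, 0.01, 0.45)

  # --- beats: integrate-and-fire around hr_mean ---
  hr_inst <- cfg$hr_mean * (1 + 0.03 * band_noise(n, fs, 0.01, 0.40))
  phase <- cumsum(hr_inst / 60) / fs
  rpeaks <- phase_crossings(phase, tt)
  if (length(rpeaks) < 3)
    stop("simulation produced fewer than 3 beats", call. = FALSE)
  beat_phase <- stats::approx(c(0, rpeaks, cfg$duration_s),
                              c(0, seq_along(rpeaks), length(rpeaks) + 1),
                              xout = tt, rule = 2)$y

  # --- channels ---
  pulse <- pulse_shape(beat_phase %% 1)
  abp <- cfg$map_mean + map_dev + 15 * pulse
  cbfv <- cfg$cbfv_mean * (1 + v_pct / 100 + 0.30 * pulse)
  o2hb_mean <- cfg$toi_mean * cfg$nthi_mean
  o2hb <- o2hb_mean * (1 + c_pct / 100)
  nthi <- cfg$nthi_mean + cfg$nthi_fluct_sd * band_noise(n, fs, 0.01, 0.40)
  toi <- o2hb / nthi
  if (any(toi <= 0 | toi > 100))
    stop("simulated TOI left (0, 100]; reduce stage gains, forcing ",
         "amplitude or noise SDs", call. = FALSE)

  dec <- function(x, rate) x[seq(1, n, by = fs / rate)]
  channels <- list(
    ABP = list(values = dec(abp, 250), fs = 250),
    CBFV = list(values = dec(cbfv, 100), fs = 100),
    TOI = list(values = dec(toi, 5), fs = 5),
    nTHI = list(values = dec(nthi, 5), fs = 5))
  if (cfg$include_ecg)
    channels$ECG <- list(values = synth_ecg(rpeaks, cfg$duration_s, 250),
                         fs = 250)

  rec <- recording(channels, rpeak_times = rpeaks,
                   condition = cfg$condition,
                   subject_id = sprintf("SIM%06d", cfg$seed %% 1000000L),
                   duration = cfg$duration_s)

  grid <- (0:128) * 2 / 256
  truth <- c(stage_responses(cfg, grid),
             list(freqs = grid, rpeak_times = rpeaks, config = cfg))
  list(recording = rec, truth = truth)
}

# times where the cumulative beat phase crosses successive integers
phase_crossings <- function(phase, tt) {
  k <- seq_len(floor(phase[length(phase)]))
  k <- k[k < phase[length(phase)]]
  idx <- findInterval(k, phase)
  frac <- (k - phase[idx]) / (phase[idx + 1] - phase[idx])
  tt[idx] + frac * (tt[2] - tt[1])
}

# impulse-like ECG: Gaussian R-wave template at each beat + small noise
synth_ecg <- function(rpeaks, duration, fs) {
  n <- round(duration * fs)
  ecg <- stats::rnorm(n, 0, 0.01)
  width <- 0.012 * fs
  half <- ceiling(4 * width)
  for (tk in rpeaks) {
    c0 <- tk * fs + 1
    i <- max(1, round(c0 - half)):min(n, round(c0 + half))
    ecg[i] <- ecg[i] + exp(-0.5 * ((i - c0) / width)^2)
  }
  ecg
}

#' Simulate a cohort with between-subject parameter jitter
#'
#' Per-subject stage gains are drawn uniformly within +/-`gain_jitter`
#' (relative) of the configured values and the stage-2 delay within
#' +/-`delay_jitter` seconds; per-subject seeds derive deterministically
#' from `seed`.
#'
#' @param n_subjects cohort size (>= 1).
#' @param cfg base `sim_config`.
#' @param seed master seed.
#' @param gain_jitter relative half-range for `g1` and `g2` (default 0.2).
#' @param delay_jitter absolute half-range for `delay_s` in seconds
#'   (default 0.3).
#' @return List of `simulate_subject()` results, one per subject.
#' @export
simulate_cohort <- function(n_subjects, cfg = sim_config(), seed = 1,
                            gain_jitter = 0.2, delay_jitter = 0.3) {
  stopifnot(n_subjects >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  jit <- function(half) stats::runif(n_subjects, -half, half)
  g1 <- cfg$g1 * (1 + jit(gain_jitter))
  g2 <- cfg$g2 * (1 + jit(gain_jitter))
  d2 <- cfg$delay_s + jit(delay_jitter)

  lapply(seq_len(n_subjects), function(i) {
    ci <- cfg
    ci$seed <- sub_seeds[i]
    ci$g1 <- g1[i]
    ci$g2 <- g2[i]
    ci$delay_s <- max(0, d2[i])
    out <- simulate_subject(ci)
    out$recording$subject_id <- sprintf("SIM%03d", i)
    out
  })
}
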