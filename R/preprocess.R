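#' Oxyhaemoglobin index from spatially resolved spectroscopy
#'
#' Computes the relative cortical oxyhaemoglobin index as the elementwise
#' product of the tissue oxygenation index (TOI) and the normalised total
#' haemoglobin index (nTHI), following the volume-fraction principle: TOI is
#' the oxygenated fraction of total haemoglobin and nTHI the relative total
#' haemoglobin, so their product tracks oxyhaemoglobin content in arbitrary
#' units.
#'
#' @param toi TOI values, in (0, 100] (a.u.).
#' @param nthi nTHI values, > 0 (a.u.), same length as `toi`.
#' @return Numeric vector, `toi * nthi` (a.u.).
#' @examples
#' compute_o2hb_srs(68, 1.00)   # 68
#' compute_o2hb_srs(66, 1.06)   # 69.96
#' @export
compute_o2hb_srs <- function(toi, nthi) {
  if (length(toi) != length(nthi))
    stop("toi and nthi must have the same length", call. = FALSE)
  if (any(nthi <= 0, na.rm = TRUE))
    stop("nthi values must be > 0", call. = FALSE)
  if (any(toi <= 0 | toi > 100, na.rm = TRUE))
    stop("toi values must lie in (0, 100]", call. = FALSE)
  toi * nthi
}

#' Beat-to-beat averaging of a continuous channel
#'
#' Reduces a uniformly sampled channel to one value per cardiac cycle by
#' time-averaging over each R-R interval: for beat k spanning
#' \[t_k, t_{k+1}) the value is the integral of the piecewise-linear
#' interpolant of the signal over that interval divided by the interval
#' length (trapezoidal rule with exact fractional endpoints). The beat
#' timestamp is the onset R-peak t_k, and the result has one fewer element
#' than `rpeak_times`.
#'
#' @param x numeric samples of the channel.
#' @param fs sampling rate of `x` in Hz.
#' @param rpeak_times strictly increasing beat onset times (s), at least 2,
#'   all within the sampled support of `x`.
#' @param t0 time of the first sample (s), default 0.
#' @return List with `beat_times` (interval onsets) and `values`.
#' @export
beat_average <- function(x, fs, rpeak_times, t0 = 0) {
  n <- length(x)
  if (length(rpeak_times) < 2)
    stop("need at least 2 R-peaks", call. = FALSE)
  if (any(diff(rpeak_times) <= 0))
    stop("zero-length or negative R-R interval", call. = FALSE)
  t_end <- t0 + (n - 1) / fs
  if (rpeak_times[1] < t0 - 1e-9 ||
      rpeak_times[length(rpeak_times)] > t_end + 1e-9)
    stop("R-peak outside signal support [", t0, ", ", t_end, "]",
         call. = FALSE)
  rp <- pmin(pmax(rpeak_times, t0), t_end)

  # cumulative integral of the linear interpolant at the sample knots,
  # then exact partial trapezoids to the (fractional) beat boundaries
  ct <- c(0, cumsum((x[-1] + x[-n]) / 2 / fs))
  pos <- (rp - t0) * fs            # 0-based fractional sample index
  i <- pmin(floor(pos), n - 2)     # left knot (0-based)
  frac <- pos - i
  xi <- x[i + 1]
  xs <- x[i + 2]
  xb <- xi + frac * (xs - xi)      # signal value at boundary
  cb <- ct[i + 1] + frac / fs * (xi + xb) / 2
  vals <- diff(cb) / diff(rp)
  list(beat_times = rp[-length(rp)], values = vals)
}

#' Detect R-peaks from an ECG channel
#'
#' Simple amplitude-threshold peak picking intended for clean laboratory or
#' synthetic ECG: samples exceeding half the 99.9th-percentile amplitude that
#' are local maxima within a 0.25 s neighbourhood are taken as R-waves. A
#' physiological rate bound is then enforced by rejecting peaks that would
#' create an R-R interval shorter than `min_rr`; intervals longer than
#' `max_rr` are kept but reported with a warning (they usually indicate missed
#' beats).
#'
#' @param ecg ECG samples.
#' @param fs sampling rate in Hz (>= 100).
#' @param min_rr,max_rr accepted R-R interval bounds in seconds
#'   (defaults 0.3 and 2.0, i.e. 30-200 bpm).
#' @param t0 time of the first sample.
#' @return Strictly increasing R-peak times in seconds.
#' @export
detect_rpeaks <- function(ecg, fs, min_rr = 0.3, max_rr = 2.0, t0 = 0) {
  if (fs < 100) stop("ECG must be sampled at >= 100 Hz", call. = FALSE)
  amp <- stats::quantile(ecg, 0.999, names = FALSE)
  base <- stats::median(ecg)
  if (!is.finite(amp) || stats::sd(ecg) == 0 || amp - base < 1e-12)
    stop("no R-peaks found: flat or featureless ECG", call. = FALSE)
  thr <- base + 0.5 * (amp - base)
  half <- max(1L, round(0.125 * fs))
  n <- length(ecg)
  cand <- which(ecg > thr)
  cand <- cand[cand > 1 & cand < n]
  is_peak <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    ecg[i] >= max(ecg[lo:hi]) && ecg[i] > ecg[i - 1] && ecg[i] >= ecg[i + 1]
  }, logical(1))
  idx <- cand[is_peak]
  if (!length(idx)) stop("no R-peaks found", call. = FALSE)

  # refractory pass: drop peaks closer than min_rr to the accepted one
  keep <- idx[1]
  dropped <- 0L
  for (i in idx[-1]) {
    if ((i - keep[length(keep)]) / fs >= min_rr) keep <- c(keep, i)
    else dropped <- dropped + 1L
  }
  if (dropped > 0)
    warning(dropped, " peak(s) rejected: R-R interval < ", min_rr, " s")
  times <- t0 + (keep - 1) / fs
  if (any(diff(times) > max_rr))
    warning(sum(diff(times) > max_rr), " R-R interval(s) exceed ", max_rr,
            " s; possible missed beats")
  times
}

#' Express a series as percentage of its mean
#'
#' Applied to CBFV and the oxyhaemoglobin index before spectral analysis so
#' gains are in %/mmHg and %/%; arterial pressure stays in mmHg. The mean is
#' taken over the analysed segment.
#'
#' @param x numeric series with non-zero mean.
#' @return `x * 100 / mean(x)`.
#' @export
normalize_percent <- function(x) {
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m == 0)
    stop("cannot normalise a zero-mean series", call. = FALSE)
  x * 100 / m
}

#' Resample an irregular beat series to a uniform grid
#'
#' Linearly interpolates beat values onto an equidistant grid starting at the
#' first beat time with spacing 1/fs, spanning \[first, last\] beat time.
#' Interior NaN gaps are bridged by linear interpolation first.
#'
#' @param values per-beat values.
#' @param times strictly increasing beat times (s), length >= 2.
#' @param fs target sampling rate, Hz (default 2, sufficient for
#'   cerebrovascular dynamics below 0.5 Hz).
#' @param units unit label carried along (`"mmHg"`, `"percent_of_mean"`,
#'   `"a.u."`, ...).
#' @param source channel label.
#' @return A `uniform_series`: list with `fs`, `t0`, `values`, `units`,
#'   `detrended`, `source`.
#' @export
resample_uniform <- function(values, times, fs = 2, units = "a.u.",
                             source = "") {
  if (length(values) != length(times))
    stop("values and times must have the same length", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 beats", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (anyNA(values))
    values <- zoo::na.approx(values, x = times, na.rm = FALSE)
  if (anyNA(values))
    stop("NaN at series boundary cannot be interpolated", call. = FALSE)
  grid <- seq(times[1], times[length(times)], by = 1 / fs)
  out <- stats::approx(times, values, xout = grid)$y
  structure(list(fs = fs, t0 = grid[1], values = out, units = units,
                 detrended = FALSE, source = source),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s: %d samples @ %g Hz [%s]%s\n",
              x$source, length(x$values), x$fs, x$units,
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' Remove a polynomial trend
#'
#' Subtracts the least-squares polynomial fit of the given order (cubic by
#' default, removing slow drifts below the analysis band). The output mean is
#' zero to numerical precision, and the operation is idempotent.
#'
#' @param x a `uniform_series` or numeric vector.
#' @param order polynomial order (default 3).
#' @return Same type as `x`, detrended.
#' @export
detrend_poly <- function(x, order = 3) {
  us <- inherits(x, "uniform_series")
  v <- if (us) x$values else x
  n <- length(v)
  if (n <= order + 1)
    stop("series too short to fit order-", order, " polynomial",
         call. = FALSE)
  if (all(v == 0)) {
    res <- v
  } else {
    tt <- seq_len(n)
    res <- stats::lm.fit(cbind(1, stats::poly(tt, order)), v)$residuals
    res <- as.numeric(res)
  }
  if (us) {
    x$values <- res
    x$detrended <- TRUE
    x
  } else res
}

#' Preprocess a recording into analysis-ready 2 Hz series
#'
#' Runs the full beat-level pipeline: R-peak selection (supplied times, else
#' ECG detection), time-averaging of each channel within R-R intervals,
#' oxyhaemoglobin index from beat-averaged TOI and nTHI, percent-of-mean
#' normalisation of CBFV and O2Hb (pressure stays in mmHg), linear
#' interpolation to a uniform `fs` Hz grid, and cubic detrending.
#'
#' @param rec a `recording`.
#' @param fs output sampling rate, Hz (default 2).
#' @param detrend_order polynomial detrend order (default 3).
#' @param rr_bounds accepted R-R interval range in seconds for ECG-based
#'   detection.
#' @return List with `beats` (data frame of per-beat values: `beat_time`,
#'   `map`, `cbfv`, `toi`, `nthi`, `o2hb`, `hr`) and `series` (named list of
#'   detrended `uniform_series`: `map`, `cbfv`, `o2hb`, plus `hr`/`etco2`
#'   when available).
#' @export
preprocess_recording <- function(rec, fs = 2, detrend_order = 3,
                                 rr_bounds = c(0.3, 2.0)) {
  validate_recording(rec)
  rp <- rec$rpeak_times
  if (is.null(rp)) {
    ecg <- rec$channels$ECG
    rp <- detect_rpeaks(ecg$values, ecg$fs,
                        min_rr = rr_bounds[1], max_rr = rr_bounds[2])
  }

  avg <- function(name) {
    ch <- rec$channels[[name]]
    v <- ch$values
    if (anyNA(v)) v <- zoo::na.approx(v, na.rm = FALSE)
    if (anyNA(v)) {
      # boundary gap: extend nearest finite value
      v <- zoo::na.fill(v, "extend")
    }
    beat_average(v, ch$fs, rp)$values
  }

  pressure <- if ("ABP" %in% names(rec$channels)) "ABP" else "MAP_beat"
  map <- avg(pressure)
  cbfv <- avg("CBFV")
  toi <- avg("TOI")
  nthi <- avg("nTHI")
  o2hb <- compute_o2hb_srs(toi, nthi)
  bt <- rp[-length(rp)]
  hr <- 60 / diff(rp)

  beats <- data.frame(beat_time = bt, map = map, cbfv = cbfv, toi = toi,
                      nthi = nthi, o2hb = o2hb, hr = hr)

  mk <- function(vals, units, source, normalize = FALSE) {
    if (normalize) vals <- normalize_percent(vals)
    detrend_poly(resample_uniform(vals, bt, fs = fs, units = units,
                                  source = source),
                 order = detrend_order)
  }
  series <- list(
    map  = mk(map,  "mmHg", pressure),
    cbfv = mk(cbfv, "percent_of_mean", "CBFV", normalize = TRUE),
    o2hb = mk(o2hb, "percent_of_mean", "O2Hb_SRS", normalize = TRUE),
    hr   = mk(hr,   "bpm", "HR"))
  if ("EtCO2" %in% names(rec$channels)) {
    et <- rec$channels$EtCO2
    tt <- (seq_along(et$values) - 1) / et$fs
    sel <- tt >= bt[1] & tt <= bt[length(bt)]
    series$etco2 <- mk_from_grid(et$values[sel], tt[sel], fs, detrend_order)
  }
  list(beats = beats, series = series, rpeak_times = rp)
}

mk_from_grid <- function(values, times, fs, detrend_order) {
  detrend_poly(resample_uniform(values, times, fs = fs, units = "mmHg",
                                source = "EtCO2"),
               order = detrend_order)
}
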