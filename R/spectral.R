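#' @title Welch spectral estimation with the standard autoregulation settings
#' @description Cross- and auto-spectral estimation by the Welch method:
#'   256-point segments, 50% overlap, Hann window, one-sided density scaling.
#'   At the 2 Hz working rate this gives the conventional 0.0078125 Hz bin
#'   spacing.
#' @name welch
NULL

# periodic Hann window
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

series_values <- function(x) {
  if (inherits(x, "uniform_series")) x$values else as.numeric(x)
}

series_fs <- function(x, fs) {
  if (inherits(x, "uniform_series")) x$fs else fs
}

# FFTs of windowed, 50%-overlapping segments: complex matrix [nperseg x K]
segment_ffts <- function(x, nperseg, overlap, window) {
  n <- length(x)
  step <- round(nperseg * (1 - overlap))
  if (step < 1) stop("overlap too large", call. = FALSE)
  if (n < nperseg)
    stop("series shorter than one segment (", nperseg, " samples)",
         call. = FALSE)
  k <- floor((n - nperseg) / step) + 1
  idx <- outer(seq_len(nperseg), (seq_len(k) - 1) * step, "+")
  seg <- matrix(x[idx], nperseg, k) * window
  stats::mvfft(seg)
}

#' Pairwise Welch auto- and cross-spectra
#'
#' Estimates one-sided auto-spectral densities of `x` and `y` and their
#' complex cross-spectral density by averaging Hann-windowed overlapping
#' segment periodograms. The cross-spectrum is `mean(Conj(X_k) * Y_k)`, so a
#' transfer function `Sxy/Sxx` has positive phase when the output leads the
#' input.
#'
#' @param x,y input and output series (`uniform_series` or numeric vectors of
#'   equal length at the same rate).
#' @param fs sampling rate in Hz (taken from `x` when it is a
#'   `uniform_series`; default 2).
#' @param nperseg segment length in samples (default 256).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param window window name; only `"hann"` (raised cosine) is implemented.
#' @return A `welch_xspec`: `freqs` (0 to fs/2, spacing fs/nperseg), `Sxx`,
#'   `Syy` (real, >= 0), `Sxy` (complex), `n_segments`, `fs`, `nperseg`.
#' @export
welch_spectra <- function(x, y, fs = 2, nperseg = 256, overlap = 0.5,
                          window = "hann") {
  window <- match.arg(window, "hann")
  fs <- series_fs(x, fs)
  xv <- series_values(x)
  yv <- series_values(y)
  if (length(xv) != length(yv))
    stop("x and y must have equal length", call. = FALSE)
  if (inherits(y, "uniform_series") && y$fs != fs)
    stop("x and y must share the sampling rate", call. = FALSE)
  w <- hann_window(nperseg)
  X <- segment_ffts(xv, nperseg, overlap, w)
  Y <- segment_ffts(yv, nperseg, overlap, w)
  k <- ncol(X)
  nbin <- nperseg %/% 2 + 1
  scale <- one_sided_scale(fs, w, nperseg)
  Sxx <- rowMeans(Mod(X[seq_len(nbin), , drop = FALSE])^2) * scale
  Syy <- rowMeans(Mod(Y[seq_len(nbin), , drop = FALSE])^2) * scale
  Sxy <- rowMeans(Conj(X[seq_len(nbin), , drop = FALSE]) *
                    Y[seq_len(nbin), , drop = FALSE]) * scale
  structure(list(freqs = (0:(nbin - 1)) * fs / nperseg,
                 Sxx = Sxx, Syy = Syy, Sxy = Sxy,
                 n_segments = k, fs = fs, nperseg = nperseg),
            class = "welch_xspec")
}

# one-sided PSD scaling: density per Hz, interior bins doubled
one_sided_scale <- function(fs, w, nperseg) {
  nbin <- nperseg %/% 2 + 1
  s <- rep(2 / (fs * sum(w^2)), nbin)
  s[1] <- s[1] / 2
  s[nbin] <- s[nbin] / 2
  s
}

#' Power spectral density (Welch)
#'
#' @param x a `uniform_series` or numeric vector.
#' @inheritParams welch_spectra
#' @return Data frame with `freq` (Hz) and `psd` (units^2/Hz).
#' @export
psd <- function(x, fs = 2, nperseg = 256, overlap = 0.5, window = "hann") {
  s <- welch_spectra(x, x, fs = fs, nperseg = nperseg, overlap = overlap,
                     window = window)
  data.frame(freq = s$freqs, psd = s$Sxx)
}

#' Joint spectral set for the three cascade signals
#'
#' One pass of Welch segmentation over the pressure, flow-velocity and
#' oxyhaemoglobin series, returning all auto-spectra (`Spp`, `Svv`, `Scc`)
#' and the cross-spectra used by the three pathways (`Spv`, `Svc`, `Spc`).
#'
#' @param map pressure series (mmHg, detrended).
#' @param cbfv flow-velocity series (% of mean, detrended).
#' @param o2hb oxyhaemoglobin series (% of mean, detrended).
#' @inheritParams welch_spectra
#' @return A `spectral_set` with `freqs`, real non-negative auto-spectra,
#'   complex cross-spectra, and `n_segments`.
#' @export
cascade_spectra <- function(map, cbfv, o2hb, fs = 2, nperseg = 256,
                            overlap = 0.5, window = "hann") {
  window <- match.arg(window, "hann")
  fs <- series_fs(map, fs)
  sigs <- list(p = series_values(map), v = series_values(cbfv),
               c = series_values(o2hb))
  len <- vapply(sigs, length, 1L)
  if (length(unique(len)) != 1)
    stop("map, cbfv and o2hb must have equal length", call. = FALSE)
  w <- hann_window(nperseg)
  F <- lapply(sigs, segment_ffts, nperseg = nperseg, overlap = overlap,
              window = w)
  nbin <- nperseg %/% 2 + 1
  scale <- one_sided_scale(fs, w, nperseg)
  take <- function(m) m[seq_len(nbin), , drop = FALSE]
  auto <- function(a) rowMeans(Mod(take(F[[a]]))^2) * scale
  cross <- function(a, b) rowMeans(Conj(take(F[[a]])) * take(F[[b]])) * scale
  structure(list(freqs = (0:(nbin - 1)) * fs / nperseg,
                 Spp = auto("p"), Svv = auto("v"), Scc = auto("c"),
                 Spv = cross("p", "v"), Svc = cross("v", "c"),
                 Spc = cross("p", "c"),
                 n_segments = ncol(F$p), fs = fs, nperseg = nperseg),
            class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("<spectral_set> %d bins, df = %g Hz, %d segment(s)\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$n_segments))
  invisible(x)
}

PATHWAYS <- data.frame(
  pathway = c("H1", "H2", "H0"),
  input = c("p", "v", "p"),
  output = c("v", "c", "c"),
  gain_units = c("%/mmHg", "%/%", "%/mmHg"),
  stringsAsFactors = FALSE)

#' Transfer function estimate from a spectral set
#'
#' H(f) = Sxy(f)/Sxx(f) for the requested input/output pair, with gain |H|,
#' phase arg(H) wrapped to (-pi, pi], and magnitude-squared coherence
#' |Sxy|^2 / (Sxx * Syy). Positive phase means the output leads the input
#' (the autoregulatory signature of the pressure-to-flow stage at low
#' frequencies). Bins with zero input power are marked invalid and excluded
#' from band summaries.
#'
#' @param spec a `spectral_set` from [cascade_spectra()], or a `welch_xspec`
#'   from [welch_spectra()] (in which case `input`/`output` are ignored and
#'   x -> y is used).
#' @param input,output signal roles among `"p"` (pressure), `"v"` (flow
#'   velocity), `"c"` (oxyhaemoglobin); or a pathway name `"H1"`, `"H2"`,
#'   `"H0"` via `pathway`.
#' @param pathway optional pathway shorthand overriding `input`/`output`.
#' @return A `tf_result`: `freqs`, complex `H`, `gain`, `phase` (rad),
#'   `coherence`, `valid` mask, `pathway`, `gain_units`, `n_segments`.
#' @export
transfer_function <- function(spec, input = "p", output = "v",
                              pathway = NULL) {
  if (inherits(spec, "welch_xspec")) {
    Sxx <- spec$Sxx; Syy <- spec$Syy; Sxy <- spec$Sxy
    pw <- pathway %||% "H0"
    units <- "output/input"
  } else if (inherits(spec, "spectral_set")) {
    if (!is.null(pathway)) {
      row <- PATHWAYS[PATHWAYS$pathway == pathway, ]
      if (!nrow(row)) stop("unknown pathway: ", pathway, call. = FALSE)
      input <- row$input; output <- row$output
    }
    pair <- paste0(input, output)
    pick <- switch(pair,
      pv = list(spec$Spp, spec$Svv, spec$Spv),
      vc = list(spec$Svv, spec$Scc, spec$Svc),
      pc = list(spec$Spp, spec$Scc, spec$Spc),
      stop("pair ", input, " -> ", output, " not present in spectral set",
           call. = FALSE))
    Sxx <- pick[[1]]; Syy <- pick[[2]]; Sxy <- pick[[3]]
    row <- PATHWAYS[PATHWAYS$input == input & PATHWAYS$output == output, ]
    pw <- pathway %||% row$pathway
    units <- row$gain_units
  } else stop("spec must be a spectral_set or welch_xspec", call. = FALSE)

  valid <- Sxx > 0 & Syy > 0
  H <- rep(NA_complex_, length(Sxx))
  coh <- rep(NA_real_, length(Sxx))
  H[valid] <- Sxy[valid] / Sxx[valid]
  coh[valid] <- Mod(Sxy[valid])^2 / (Sxx[valid] * Syy[valid])
  structure(list(freqs = spec$freqs, H = H, gain = Mod(H), phase = Arg(H),
                 coherence = coh, valid = valid, pathway = pw,
                 gain_units = units, n_segments = spec$n_segments),
            class = "tf_result")
}

#' @export
print.tf_result <- function(x, ...) {
  cat(sprintf("<tf_result> %s (%s), %d bins, %d segment(s)\n",
              x$pathway, x$gain_units, length(x$freqs), x$n_segments))
  invisible(x)
}

# wrap angles to (-pi, pi]
wrap_phase <- function(p) {
  out <- (p + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}
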