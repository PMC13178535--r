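#' Analysis frequency bands
#'
#' Very-low, low and high frequency bands used for resting spontaneous
#' oscillations, plus `F005`, the two spectral bins flanking the 0.05 Hz
#' forced-oscillation frequency of the repeated sit-stand manoeuvre
#' (0.046875 and 0.0546875 Hz on the 2 Hz / 256-point grid). Band edges are
#' left-closed, right-open; a bin belongs to a band iff its centre frequency
#' falls inside the interval.
#'
#' @format Named list of `c(low, high)` ranges in Hz.
#' @export
default_bands <- function() {
  list(VLF = c(0.02, 0.07), LF = c(0.07, 0.20), HF = c(0.20, 0.35))
}

# bins making up the F005 band: the two grid frequencies flanking 0.05 Hz
f005_bins <- function(freqs, f0 = 0.05) {
  below <- max(which(freqs < f0))
  c(below, below + 1L)
}

#' Combine two transfer-function stages into a series cascade
#'
#' For a series linear system the overall response is the product of the
#' stage responses: the cascade gain is the product of the component gains,
#' the cascade phase is the sum of the component phases (re-wrapped to
#' (-pi, pi\]), and the cascade coherence is taken as the product of the
#' component magnitude-squared coherences, which is bounded above by either
#' component's coherence.
#'
#' @param h1 `tf_result` for the upstream stage (pressure -> flow velocity).
#' @param h2 `tf_result` for the downstream stage (flow velocity -> O2Hb).
#' @return A `cascade_result` with `freqs`, complex `H`, `gain`, `phase`,
#'   `coherence`, `valid`, and the component results as `h1`, `h2`.
#' @examples
#' \dontrun{
#' hc <- cascade_combine(transfer_function(spec, pathway = "H1"),
#'                       transfer_function(spec, pathway = "H2"))
#' }
#' @export
cascade_combine <- function(h1, h2) {
  stopifnot(inherits(h1, "tf_result"), inherits(h2, "tf_result"))
  if (length(h1$freqs) != length(h2$freqs) ||
      any(abs(h1$freqs - h2$freqs) > 1e-12))
    stop("component transfer functions must share the frequency grid",
         call. = FALSE)
  H <- h1$H * h2$H
  structure(list(freqs = h1$freqs, H = H,
                 gain = h1$gain * h2$gain,
                 phase = wrap_phase(h1$phase + h2$phase),
                 coherence = h1$coherence * h2$coherence,
                 valid = h1$valid & h2$valid,
                 pathway = "Hc", gain_units = "%/mmHg",
                 n_segments = h1$n_segments,
                 h1 = h1, h2 = h2),
            class = c("cascade_result", "tf_result"))
}

#' Phase-wrapping exclusion mask
#'
#' Resting spontaneous recordings occasionally show negative
#' pressure-to-flow phase at the lowest frequencies where the true phase
#' lead approaches +pi and wraps. Rather than unwrapping, such bins
#' (frequency < `f_max` with negative upstream phase) are excluded from
#' phase band means of the upstream stage and of the cascade. Gain and
#' coherence means are unaffected, and the rule applies only at rest: for
#' sit-stand data the mask is all-true.
#'
#' @param tf a `tf_result` for the pressure-to-flow stage.
#' @param condition `"rest"` or `"sit_stand"`.
#' @param f_max upper frequency bound of the rule (default 0.10 Hz).
#' @return Logical vector per bin: `TRUE` = keep for phase averaging.
#' @export
phase_exclusion_mask <- function(tf, condition = c("rest", "sit_stand"),
                                 f_max = 0.10) {
  condition <- match.arg(condition)
  keep <- rep(TRUE, length(tf$freqs))
  if (condition == "rest")
    keep[tf$freqs < f_max & !is.na(tf$phase) & tf$phase < 0] <- FALSE
  keep
}

#' Band summaries of a transfer function
#'
#' Arithmetic means of gain, phase and coherence over the bins of each
#' analysis band. At rest the summaries cover the VLF, LF and HF bands; for
#' sit-stand data a single `F005` summary averages exactly the two bins
#' flanking 0.05 Hz. Phase means honour an exclusion mask (see
#' [phase_exclusion_mask()]); per the wrap-handling convention the mean is
#' the arithmetic mean of wrapped per-bin phases, not a circular mean. The
#' DC bin is never part of a band. A band with no valid bins yields `NA`
#' (undefined), not zero.
#'
#' @param tf a `tf_result` or `cascade_result`.
#' @param condition `"rest"` (VLF/LF/HF) or `"sit_stand"` (F005).
#' @param spec optional `spectral_set` supplying the input-signal PSD band
#'   mean (`psd_input` column).
#' @param phase_keep optional logical mask of bins to keep for the phase
#'   mean; defaults to all-true. For the upstream stage and the cascade at
#'   rest, pass `phase_exclusion_mask()` of the upstream stage.
#' @param bands band definition list (default [default_bands()]).
#' @return Data frame with one row per band: `pathway`, `band`, `gain`,
#'   `phase`, `coherence`, `psd_input`, `n_bins`, `n_phase_bins`.
#' @export
band_summary <- function(tf, condition = c("rest", "sit_stand"),
                         spec = NULL, phase_keep = NULL,
                         bands = default_bands()) {
  condition <- match.arg(condition)
  freqs <- tf$freqs
  if (is.null(phase_keep)) phase_keep <- rep(TRUE, length(freqs))
  stopifnot(length(phase_keep) == length(freqs))

  psd_in <- NULL
  if (!is.null(spec)) {
    psd_in <- switch(tf$pathway, H1 = spec$Spp, H2 = spec$Svv,
                     H0 = spec$Spp, Hc = spec$Spp)
  }

  bin_sets <- if (condition == "rest") {
    lapply(bands, function(b) which(freqs >= b[1] & freqs < b[2] & freqs > 0))
  } else {
    list(F005 = f005_bins(freqs))
  }

  rows <- lapply(names(bin_sets), function(bn) {
    sel <- bin_sets[[bn]]
    sel <- sel[tf$valid[sel]]
    psel <- sel[phase_keep[sel]]
    if (!length(sel)) {
      return(data.frame(pathway = tf$pathway, band = bn, gain = NA_real_,
                        phase = NA_real_, coherence = NA_real_,
                        psd_input = NA_real_, n_bins = 0L,
                        n_phase_bins = 0L))
    }
    data.frame(
      pathway = tf$pathway, band = bn,
      gain = mean(tf$gain[sel]),
      phase = if (length(psel)) mean(tf$phase[psel]) else NA_real_,
      coherence = mean(tf$coherence[sel]),
      psd_input = if (is.null(psd_in)) NA_real_ else mean(psd_in[sel]),
      n_bins = length(sel), n_phase_bins = length(psel))
  })
  do.call(rbind, rows)
}

#' Band summaries of power spectral densities
#'
#' @param spec a `spectral_set`.
#' @inheritParams band_summary
#' @return Data frame with one row per signal x band: `signal`, `band`,
#'   `psd`, `n_bins`.
#' @export
psd_band_summary <- function(spec, condition = c("rest", "sit_stand"),
                             bands = default_bands()) {
  condition <- match.arg(condition)
  freqs <- spec$freqs
  bin_sets <- if (condition == "rest") {
    lapply(bands, function(b) which(freqs >= b[1] & freqs < b[2] & freqs > 0))
  } else {
    list(F005 = f005_bins(freqs))
  }
  sig <- list(MAP = spec$Spp, CBFV = spec$Svv, O2Hb_SRS = spec$Scc)
  rows <- list()
  for (s in names(sig)) for (bn in names(bin_sets)) {
    sel <- bin_sets[[bn]]
    rows[[paste(s, bn)]] <- data.frame(
      signal = s, band = bn,
      psd = if (length(sel)) mean(sig[[s]][sel]) else NA_real_,
      n_bins = length(sel))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Significant-coupling flag
#'
#' A band shows significant linear coupling when its mean magnitude-squared
#' coherence strictly exceeds the critical threshold (default 0.34, the 95%
#' confidence limit for five 50%-overlapping Hann windows; see
#' [coherence_critical_value()]). Undefined coherence yields `NA`.
#'
#' @param coherence band-mean coherence value(s).
#' @param threshold critical coherence (default 0.34).
#' @return Logical vector; `NA` where coherence is undefined.
#' @export
coupling_significance <- function(coherence, threshold = 0.34) {
  ifelse(is.na(coherence), NA, coherence > threshold)
}

#' Cohort counts of significant coupling
#'
#' Number and percentage of subjects whose band-mean coherence exceeds the
#' critical threshold, per pathway and band. Subjects with undefined
#' coherence in a cell are excluded from that cell's denominator with a
#' message.
#'
#' @param results result table with columns `subject_id`, `pathway`, `band`,
#'   `coherence` (one row per subject x pathway x band).
#' @param threshold critical coherence (default 0.34).
#' @return Data frame with `pathway`, `band`, `n_significant`, `n_total`,
#'   `percent`.
#' @export
cohort_coupling_counts <- function(results, threshold = 0.34) {
  stopifnot(all(c("pathway", "band", "coherence") %in% names(results)))
  flag <- coupling_significance(results$coherence, threshold)
  n_undef <- sum(is.na(flag))
  if (n_undef > 0)
    message(n_undef, " subject-band cell(s) with undefined coherence ",
            "excluded from denominators")
  key <- interaction(results$pathway, results$band, drop = TRUE, sep = "|")
  n_sig <- tapply(flag, key, function(z) sum(z, na.rm = TRUE))
  n_tot <- tapply(flag, key, function(z) sum(!is.na(z)))
  parts <- strsplit(names(n_sig), "|", fixed = TRUE)
  out <- data.frame(
    pathway = vapply(parts, `[`, "", 1),
    band = vapply(parts, `[`, "", 2),
    n_significant = as.integer(n_sig),
    n_total = as.integer(n_tot),
    percent = 100 * as.integer(n_sig) / as.integer(n_tot))
  rownames(out) <- NULL
  out[order(out$pathway, out$band), ]
}

#' Monte Carlo critical coherence value
#'
#' Estimates the (1 - alpha) confidence limit of band-averaged
#' magnitude-squared coherence between two independent white Gaussian noise
#' series, processed through exactly the package's Welch estimator with the
#' given segmentation. Records are sized to give exactly `n_segments`
#' 50%-overlapping windows. The statistic is the mean MSC over a band of
#' `band_bins` adjacent bins (default 6, the width of the VLF band on the
#' 2 Hz / 256-point grid, matching how the threshold is applied to band-mean
#' coherence); its 95th percentile for five windows is the conventional
#' critical value 0.34.
#'
#' @param n_segments number of 50%-overlapping windows (>= 2).
#' @param alpha significance level (default 0.05).
#' @param n_sim number of simulated independent pairs (default 5000; a
#'   warning is issued below 1000).
#' @param seed RNG seed for reproducibility.
#' @param nperseg segment length (default 256).
#' @param fs sampling rate (default 2 Hz).
#' @param band_bins number of adjacent bins averaged per realisation
#'   (default 6).
#' @param band_start_hz lower edge of the averaged band (default 0.02 Hz).
#' @return The critical coherence value (scalar).
#' @export
coherence_critical_value <- function(n_segments, alpha = 0.05, n_sim = 5000,
                                     seed = 1, nperseg = 256, fs = 2,
                                     band_bins = 6, band_start_hz = 0.02) {
  stopifnot(n_segments >= 2)
  if (n_sim < 1000)
    warning("n_sim < 1000: critical value will be noisy")
  n <- nperseg / 2 * (n_segments + 1)
  freqs <- (0:(nperseg / 2)) * fs / nperseg
  first <- min(which(freqs >= band_start_hz))
  sel <- first:(first + band_bins - 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  stat <- numeric(n_sim)
  chunk <- 500L
  done <- 0L
  while (done < n_sim) {
    m <- min(chunk, n_sim - done)
    for (i in seq_len(m)) {
      s <- welch_spectra(stats::rnorm(n), stats::rnorm(n), fs = fs,
                         nperseg = nperseg)
      msc <- Mod(s$Sxy[sel])^2 / (s$Sxx[sel] * s$Syy[sel])
      stat[done + i] <- mean(msc)
    }
    done <- done + m
  }
  unname(stats::quantile(stat, 1 - alpha))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
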