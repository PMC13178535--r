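#' Compare cascade-derived and directly estimated indices across subjects
#'
#' For each band and metric (gain, phase, coherence), correlates the
#' cascade-model value (product/sum of the stage estimates) with the
#' directly estimated total-pathway value across subjects: Pearson r with a
#' Fisher-z 95% confidence interval, the coefficient of determination from
#' the least-squares regression of the total-pathway index on the cascade
#' index (equal to r^2 for simple regression), and a two-sided p-value.
#'
#' @param results result table from [analyze_cohort()] (needs pathways
#'   `"Hc"` and `"H0"`).
#' @param conf_level confidence level (default 0.95).
#' @return Data frame with `metric`, `band`, `condition`, `n`, `pearson_r`,
#'   `ci_low`, `ci_high`, `r_squared`, `p_value`, `note`.
#' @export
compare_cascade_total <- function(results, conf_level = 0.95) {
  need <- c("subject_id", "condition", "pathway", "band")
  stopifnot(all(need %in% names(results)))
  h0 <- results[results$pathway == "H0", ]
  hc <- results[results$pathway == "Hc", ]
  key <- function(d) paste(d$subject_id, d$condition, d$band, sep = "|")
  m <- match(key(h0), key(hc))
  h0 <- h0[!is.na(m), ]
  hc <- hc[m[!is.na(m)], ]

  combos <- unique(h0[c("condition", "band")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cond <- combos$condition[i]; band <- combos$band[i]
    sel <- h0$condition == cond & h0$band == band
    for (metric in c("gain", "phase", "coherence")) {
      x <- hc[[metric]][sel]   # cascade (predictor)
      y <- h0[[metric]][sel]   # direct total
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      row <- data.frame(metric = metric, band = band, condition = cond,
                        n = n, pearson_r = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, note = "")
      if (n < 3) {
        row$note <- "undefined: fewer than 3 subjects"
      } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        row$note <- "undefined: zero variance"
      } else {
        ct <- stats::cor.test(x, y, conf.level = conf_level)
        row$pearson_r <- unname(ct$estimate)
        if (!is.null(ct$conf.int)) {
          row$ci_low <- ct$conf.int[1]
          row$ci_high <- ct$conf.int[2]
        }
        row$r_squared <- unname(ct$estimate)^2
        row$p_value <- ct$p.value
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write report tables (and optional figures) for a cohort analysis
#'
#' Emits tidy CSVs: the per-subject result table, the cascade-vs-total
#' comparison table, and the significant-coupling counts. Optionally plots
#' group-mean gain/phase/coherence spectra with across-subject 95%
#' confidence intervals.
#'
#' @param results result table from [analyze_cohort()].
#' @param out_dir output directory (created if needed).
#' @param comparisons optional output of [compare_cascade_total()]; computed
#'   from `results` when `NULL`.
#' @param threshold critical coherence for the coupling counts.
#' @param spectra optional list of `analysis` objects for the figure.
#' @param plots write a PNG of group-mean spectra?
#' @return Named character vector of written file paths, invisibly.
#' @export
make_report <- function(results, out_dir, comparisons = NULL,
                        threshold = 0.34, spectra = NULL, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(comparisons)) comparisons <- compare_cascade_total(results)
  paths <- c(results = file.path(out_dir, "results.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"),
             coupling = file.path(out_dir, "coupling_counts.csv"))
  write_results(results, paths["results"])
  write_results(comparisons, paths["comparisons"])
  write_results(cohort_coupling_counts(results, threshold),
                paths["coupling"])
  if (plots && !is.null(spectra)) {
    paths <- c(paths, figure = file.path(out_dir, "group_spectra.png"))
    plot_group_spectra(spectra, paths["figure"])
  }
  invisible(paths)
}

# group-mean gain/phase/coherence spectra with 95% CI ribbons
plot_group_spectra <- function(analyses, path) {
  tfs <- c("H1", "H2", "H0", "Hc")
  metrics <- c("gain", "phase", "coherence")
  freqs <- analyses[[1]]$tf$H1$freqs
  grDevices::png(path, width = 1200, height = 900, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(3, 4), mar = c(3.5, 3.5, 2, 0.5),
                mgp = c(2.2, 0.7, 0))
  for (metric in metrics) for (p in tfs) {
    vals <- vapply(analyses, function(a) a$tf[[p]][[metric]],
                   numeric(length(freqs)))
    mu <- rowMeans(vals, na.rm = TRUE)
    se <- apply(vals, 1, stats::sd, na.rm = TRUE) / sqrt(ncol(vals))
    sel <- freqs > 0 & freqs <= 0.5
    graphics::plot(freqs[sel], mu[sel], type = "n", xlab = "Frequency (Hz)",
                   ylab = metric, main = p)
    graphics::polygon(c(freqs[sel], rev(freqs[sel])),
                      c(mu[sel] + 1.96 * se[sel],
                        rev(mu[sel] - 1.96 * se[sel])),
                      col = "grey85", border = NA)
    graphics::lines(freqs[sel], mu[sel], lwd = 1.5)
  }
  invisible(path)
}
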