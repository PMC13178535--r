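#' Multichannel haemodynamic recording
#'
#' A `recording` bundles raw continuous physiological channels (each a vector
#' of samples with its own sampling rate), optional R-peak event times, and
#' session metadata. All channels share the time origin t = 0 at the first
#' sample; times are seconds from recording start.
#'
#' Recognised channel names are `ABP` (arterial pressure waveform, mmHg),
#' `MAP_beat` (beat-to-beat mean arterial pressure held between beats, mmHg),
#' `CBFV` (cerebral blood flow velocity, cm/s), `TOI` (tissue oxygenation
#' index, a.u.), `nTHI` (normalised total haemoglobin index, a.u.), `ECG`,
#' `EtCO2` (mmHg) and `HR` (bpm). Analysis requires a pressure channel (`ABP`
#' or `MAP_beat`), `CBFV`, `TOI`, `nTHI`, and either `ECG` or `rpeak_times`.
#'
#' Missing-data gaps (e.g. finger-cuff recalibration dropouts) are stored as
#' `NaN` runs and linearly interpolated downstream; they are summarised in the
#' `gaps` attribute of each channel on read/validation.
#'
#' @param channels named list; each element a list with `values` (numeric) and
#'   `fs` (sampling rate, Hz > 0).
#' @param rpeak_times strictly increasing R-peak times in seconds, or `NULL`
#'   if an `ECG` channel is supplied instead.
#' @param condition `"rest"` or `"sit_stand"`.
#' @param subject_id character scalar.
#' @param duration recording length in seconds.
#' @return An object of class `recording`.
#' @seealso [read_recording()], [write_recording()], [simulate_subject()]
#' @export
recording <- function(channels, rpeak_times = NULL,
                      condition = c("rest", "sit_stand"),
                      subject_id = "S01", duration) {
  condition <- match.arg(condition)
  rec <- structure(
    list(channels = channels, rpeak_times = rpeak_times,
         condition = condition, subject_id = subject_id,
         duration = duration),
    class = "recording")
  validate_recording(rec)
}

CHANNEL_NAMES <- c("ABP", "MAP_beat", "CBFV", "TOI", "nTHI", "ECG",
                   "EtCO2", "HR")

#' Validate a recording against its invariants
#'
#' Checks channel names, sampling rates, lengths against the declared
#' duration, R-peak monotonicity and range, TOI/nTHI physiological bounds,
#' and the presence of the channels required for cascade analysis. NaN runs
#' are annotated as a `gaps` attribute (a two-column matrix of run start/end
#' sample indices) on each channel.
#'
#' @param rec a `recording`.
#' @return `rec`, invisibly modified with gap annotations.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  nm <- names(rec$channels)
  if (is.null(nm) || any(nm == ""))
    stop("all channels must be named", call. = FALSE)
  bad <- setdiff(nm, CHANNEL_NAMES)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)

  mandatory_missing <- character()
  if (!any(c("ABP", "MAP_beat") %in% nm)) mandatory_missing <- "ABP/MAP_beat"
  for (ch in c("CBFV", "TOI", "nTHI"))
    if (!ch %in% nm) mandatory_missing <- c(mandatory_missing, ch)
  if (!"ECG" %in% nm && is.null(rec$rpeak_times))
    mandatory_missing <- c(mandatory_missing, "ECG or rpeak_times")
  if (length(mandatory_missing))
    stop("schema error: missing mandatory channel(s): ",
         paste(mandatory_missing, collapse = ", "), call. = FALSE)

  if (!is.numeric(rec$duration) || rec$duration <= 0)
    stop("duration must be a positive number of seconds", call. = FALSE)

  for (ch in nm) {
    x <- rec$channels[[ch]]
    if (is.null(x$values) || is.null(x$fs))
      stop("channel ", ch, " must have $values and $fs", call. = FALSE)
    if (x$fs <= 0) stop("channel ", ch, ": sampling rate must be > 0",
                        call. = FALSE)
    n_expect <- round(rec$duration * x$fs)
    if (abs(length(x$values) - n_expect) > 1)
      stop("channel ", ch, ": length ", length(x$values),
           " inconsistent with duration * rate = ", n_expect, call. = FALSE)
    rec$channels[[ch]]$gaps <- nan_runs(x$values)
  }

  toi <- rec$channels[["TOI"]]$values
  if (any(toi <= 0 | toi > 100, na.rm = TRUE))
    stop("TOI values must lie in (0, 100]", call. = FALSE)
  nthi <- rec$channels[["nTHI"]]$values
  if (any(nthi <= 0, na.rm = TRUE))
    stop("nTHI values must be > 0", call. = FALSE)

  rp <- rec$rpeak_times
  if (!is.null(rp)) {
    if (any(diff(rp) <= 0))
      stop("rpeak_times must be strictly increasing", call. = FALSE)
    if (rp[1] < 0 || rp[length(rp)] > rec$duration)
      stop("rpeak_times must lie within [0, duration]", call. = FALSE)
  }
  invisible(rec)
}

# start/end indices of NaN runs in a vector (0-row matrix when none)
nan_runs <- function(x) {
  isn <- is.nan(x)
  if (!any(isn)) return(matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("start", "end"))))
  r <- rle(isn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> subject", x$subject_id, "|", x$condition, "|",
      x$duration, "s\n")
  for (ch in names(x$channels)) {
    c_ <- x$channels[[ch]]
    cat(sprintf("  %-8s %8d samples @ %g Hz\n", ch, length(c_$values), c_$fs))
  }
  if (!is.null(x$rpeak_times))
    cat("  rpeaks  ", length(x$rpeak_times), "events\n")
  invisible(x)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.nan(x)] <- "NaN"
  out[is.na(x) & !is.nan(x)] <- ""
  out
}

#' Write a recording to a self-describing CSV file
#'
#' UTF-8 comma-delimited, one file per subject-condition: a `#`-prefixed
#' key-value header block (metadata plus one `#channel,<name>,<rate>` line per
#' channel) followed by a data matrix with one column per channel and one for
#' R-peak times. Shorter columns are padded with empty fields at the end;
#' genuine missing samples are written as `NaN`. Values carry 17 significant
#' digits so write -> read round-trips are lossless.
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  cols <- lapply(rec$channels, function(ch) fmt_num(ch$values))
  if (!is.null(rec$rpeak_times))
    cols$rpeak_times <- fmt_num(rec$rpeak_times)
  nmax <- max(vapply(cols, length, 1L))
  cols <- lapply(cols, function(v) c(v, rep("", nmax - length(v))))

  hdr <- c("#cascade_recording,1",
           paste0("#subject_id,", rec$subject_id),
           paste0("#condition,", rec$condition),
           paste0("#duration,", fmt_num(rec$duration)),
           vapply(names(rec$channels), function(ch)
             paste0("#channel,", ch, ",", fmt_num(rec$channels[[ch]]$fs)),
             character(1)))

  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(do.call(paste, c(unname(cols), sep = ",")), con)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' The declared per-channel sampling rate is treated as authoritative; no
#' resampling happens on load. Interior `NaN` runs are kept and annotated as
#' gaps; trailing empty fields are column padding and are dropped.
#'
#' @param path file path.
#' @return A validated `recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  if (!length(hdr) || !startsWith(hdr[1], "#cascade_recording"))
    stop("format error: not a cascade recording file", call. = FALSE)

  meta <- list()
  ch_fs <- numeric()
  for (h in hdr[-1]) {
    parts <- strsplit(sub("^#", "", h), ",", fixed = TRUE)[[1]]
    if (parts[1] == "channel") {
      ch_fs[parts[2]] <- as.numeric(parts[3])
    } else {
      meta[[parts[1]]] <- parts[2]
    }
  }

  body <- lines[!is_hdr]
  col_names <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  mat <- matrix("", length(cells), length(col_names))
  for (i in seq_along(cells))
    mat[i, seq_along(cells[[i]])] <- cells[[i]]

  parse_col <- function(j) {
    v <- mat[, j]
    num <- suppressWarnings(as.numeric(v))
    num[v == "NaN"] <- NaN
    # trailing blank fields are padding
    nonblank <- which(v != "")
    if (!length(nonblank)) return(numeric())
    num <- num[seq_len(max(nonblank))]
    if (any(is.na(num) & !is.nan(num)))
      stop("format error: non-numeric or interior blank field in column ",
           col_names[j], call. = FALSE)
    num
  }

  channels <- list()
  rpeaks <- NULL
  for (j in seq_along(col_names)) {
    cn <- col_names[j]
    if (cn == "rpeak_times") {
      rpeaks <- parse_col(j)
      if (any(diff(rpeaks) <= 0))
        stop("format error: non-monotone rpeak_times column", call. = FALSE)
    } else {
      if (!cn %in% names(ch_fs))
        stop("format error: column ", cn, " has no #channel header line",
             call. = FALSE)
      channels[[cn]] <- list(values = parse_col(j), fs = ch_fs[[cn]])
    }
  }

  recording(channels, rpeak_times = rpeaks,
            condition = meta$condition %||% "rest",
            subject_id = meta$subject_id %||% "S01",
            duration = as.numeric(meta$duration))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read tidy result tables
#'
#' Result tables are plain data frames keyed by
#' (`subject_id`, `condition`, `pathway`, `band`) with numeric columns such as
#' `gain`, `phase`, `coherence`, `psd_input` and a logical `significant` flag.
#' Numeric values are written with 17 significant digits so
#' read(write(x)) == x on stored precision.
#'
#' @param tbl a data frame.
#' @param path output CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_results <- function(tbl, path) {
  stopifnot(is.data.frame(tbl))
  out <- tbl
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
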