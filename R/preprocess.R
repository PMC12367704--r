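# Zero-phase Butterworth filtering, band decomposition and windowing.
#
# All filtering in the package (including the synthetic generator) goes
# through bp_filter() so generation and analysis share one filter family:
# a 4th-order Butterworth bandpass applied forward-backward with
# signal::filtfilt (zero net phase, effective 8th order).

bp_filter <- function(x, f_lo, f_hi, fs) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_hi <= fs / 2)
  bt <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  signal::filtfilt(bt, x)
}

#' Construct an EEG recording object
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channels channel labels, one per row of `data`.
#' @param subject_id subject identifier.
#' @param group group label, `"HC"` or `"SCZ"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          subject_id = "S1", group = c("HC", "SCZ")) {
  group <- match.arg(group)
  data <- as.matrix(data)
  if (is.null(channels))
    stop("channel labels are required (rownames of `data` or `channels`)")
  if (nrow(data) != length(channels))
    stop("`data` must have exactly one row per channel: ",
         nrow(data), " rows vs ", length(channels), " labels")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  rownames(data) <- channels
  structure(list(subject_id = subject_id, group = group, fs = fs,
                 channels = channels, data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, length(x$channels),
              ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Read a recording from a text matrix file
#'
#' Reads a plain-text numeric matrix (samples x channels, whitespace- or
#' comma-delimited, optional header row of channel labels) into an
#' [eeg_recording()].
#'
#' @param path file path.
#' @param fs sampling rate in Hz of the stored signal.
#' @param channels expected channel labels; when the file has a header the
#'   columns are matched against it, otherwise this declares column order.
#' @param subject_id,group metadata attached to the recording.
#' @return An `eeg_recording`.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs, channels = default_channels(),
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           group = "HC") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- {
    fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
    any(is.na(suppressWarnings(as.numeric(fields))))
  }
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           check.names = FALSE)
  if (!all(vapply(tab, is.numeric, logical(1L))))
    stop("non-numeric entries in ", path)
  if (ncol(tab) != length(channels))
    stop(sprintf("%s: expected %d channel columns, found %d",
                 path, length(channels), ncol(tab)))
  if (has_header) {
    miss <- setdiff(channels, names(tab))
    if (length(miss))
      stop(path, ": header lacks channel(s): ", paste(miss, collapse = ", "))
    tab <- tab[, channels, drop = FALSE]
  }
  eeg_recording(t(as.matrix(tab)), fs = fs, channels = channels,
                subject_id = subject_id, group = group)
}

#' Write a recording as a text matrix file
#'
#' Samples x channels, comma-delimited, header row of channel labels.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param digits significant digits retained (text round-trip precision).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- signif(t(rec$data), digits)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = rec$channels, quote = FALSE)
  invisible(path)
}

#' Broadband filter and average reference
#'
#' Filters every channel to the analysis range `[f_n, f_m]` with a
#' zero-phase Butterworth bandpass, then subtracts the across-channel mean
#' at every time point (average reference), so the output channel mean is
#' zero at every sample.
#'
#' @param rec an `eeg_recording`.
#' @param bounds a [spectral_bounds()] list.
#' @return The filtered, re-referenced `eeg_recording`.
#' @export
bandpass_and_reference <- function(rec, bounds = spectral_bounds()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * bounds$f_m)
    stop("sampling rate must exceed twice the upper analysis bound")
  if (ncol(rec$data) < 3 * rec$fs)
    stop("recording shorter than the filter warm-up length (3 s)")
  filt <- t(apply(rec$data, 1, bp_filter, f_lo = bounds$f_n,
                  f_hi = bounds$f_m, fs = rec$fs))
  filt <- sweep(filt, 2, colMeans(filt))
  rec$data <- filt
  rownames(rec$data) <- rec$channels
  rec
}

#' Decompose a recording into frequency bands
#'
#' Applies the same zero-phase Butterworth bandpass once per band,
#' producing one filtered signal per band with the shape of the input.
#'
#' @param rec an `eeg_recording` (typically already broadband-filtered and
#'   re-referenced).
#' @param bands band definition data.frame, see [eeg_bands()].
#' @return Named list (one entry per band) of channels x samples matrices.
#' @export
band_decompose <- function(rec, bands = eeg_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_bands(bands, rec$fs)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    m <- t(apply(rec$data, 1, bp_filter, f_lo = bands$f_lo[i],
                 f_hi = bands$f_hi[i], fs = rec$fs))
    rownames(m) <- rec$channels
    m
  })
  names(out) <- bands$band
  out
}

#' Segment a recording and its band signals into windows
#'
#' Cuts the broadband signal and every band-filtered signal into
#' non-overlapping windows of `window_length_s` seconds, contiguous from
#' sample 1; a trailing remainder shorter than one window is dropped.
#'
#' @param rec the broadband `eeg_recording`.
#' @param band_signals named list of band matrices from [band_decompose()].
#' @param window_length_s window length in seconds; `window_length_s * fs`
#'   must be an integer.
#' @return An object of class `eeg_epochs`: list with `broadband`
#'   (window x channel x sample array), `bands` (band x window x channel x
#'   sample array), `subject_id`, `group`, `fs`, `channels`,
#'   `window_length_s`, `n_windows`.
#' @export
segment_windows <- function(rec, band_signals, window_length_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- window_length_s * rec$fs
  if (abs(w - round(w)) > 1e-9)
    stop("window_length_s * fs must be an integer number of samples")
  w <- as.integer(round(w))
  n <- ncol(rec$data)
  n_win <- n %/% w
  if (n_win < 1L)
    stop("recording shorter than one window")
  n_ch <- length(rec$channels)
  cut3 <- function(m) {
    # channels x samples -> window x channel x sample
    a <- array(NA_real_, dim = c(n_win, n_ch, w))
    for (k in seq_len(n_win))
      a[k, , ] <- m[, ((k - 1L) * w + 1L):(k * w), drop = FALSE]
    a
  }
  bb <- cut3(rec$data)
  bd <- array(NA_real_, dim = c(length(band_signals), n_win, n_ch, w),
              dimnames = list(names(band_signals), NULL, rec$channels, NULL))
  for (b in seq_along(band_signals))
    bd[b, , , ] <- cut3(band_signals[[b]])
  structure(list(subject_id = rec$subject_id, group = rec$group,
                 fs = rec$fs, channels = rec$channels,
                 window_length_s = window_length_s, n_windows = n_win,
                 broadband = bb, bands = bd),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s [%s]: %d windows of %g s, %d channels, %d bands\n",
              x$subject_id, x$group, x$n_windows, x$window_length_s,
              length(x$channels), dim(x$bands)[1]))
  invisible(x)
}

#' Full preprocessing of one recording
#'
#' Convenience wrapper running the fixed processing order: broadband
#' filter, average reference, band decomposition, segmentation.
#'
#' @inheritParams bandpass_and_reference
#' @inheritParams band_decompose
#' @inheritParams segment_windows
#' @return An `eeg_epochs` object.
#' @export
preprocess_recording <- function(rec, window_length_s = 4,
                                 bands = eeg_bands(),
                                 bounds = spectral_bounds()) {
  rec <- bandpass_and_reference(rec, bounds)
  segment_windows(rec, band_decompose(rec, bands), window_length_s)
}
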