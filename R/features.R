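# Window-level feature families: relative band power (RP), fuzzy entropy
# (FuzEn), phase lag index (PLI), and the canonical feature table.

#' One-sided periodogram of a window
#'
#' FFT periodogram on the discrete grid `k * fs / N`, normalized so the
#' bins sum to the mean square of the signal (Parseval identity).
#'
#' @param x numeric vector, one channel of one window.
#' @param fs sampling rate in Hz.
#' @return List with `freq` (Hz, from 0 to Nyquist) and `power`
#'   (non-negative spectral mass per bin).
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2L) stop("signal must have at least 2 samples")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  X <- fft(x)
  half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(half)])^2 / n^2
  # fold negative frequencies onto positive; bin 0 (and Nyquist when n is
  # even) have no mirror image
  inner <- 2:(half - 1L)
  if (n %% 2 == 1L) inner <- 2:half
  p[inner] <- 2 * p[inner]
  list(freq = (seq_len(half) - 1L) * fs / n, power = p)
}

# indices of spectrum bins belonging to a band; bands are half-open
# [f_lo, f_hi) except the last analysis band, closed at f_m
band_bins <- function(freq, f_lo, f_hi, close_upper = FALSE) {
  if (close_upper)
    which(freq >= f_lo - 1e-9 & freq <= f_hi + 1e-9)
  else
    which(freq >= f_lo - 1e-9 & freq < f_hi - 1e-9)
}

#' Relative power of one band
#'
#' Fraction of spectral mass in the band relative to the whole analysis
#' range, rescaled by the ratio of analysis bandwidth to band bandwidth,
#' so a flat spectrum scores 1 in every band. Bandwidths are measured on
#' the discrete frequency grid (number of bins x bin width), which makes
#' the flat-spectrum and sum identities exact on any window length.
#'
#' @param spectrum output of [power_spectrum()].
#' @param band one-row band definition (see [eeg_bands()]).
#' @param bounds analysis bounds, see [spectral_bounds()]; the band whose
#'   upper edge touches `f_m` is treated as closed.
#' @return Scalar relative power (non-negative).
#' @export
relative_power <- function(spectrum, band, bounds = spectral_bounds()) {
  close_up <- abs(band$f_hi - bounds$f_m) < 1e-9
  bi <- band_bins(spectrum$freq, band$f_lo, band$f_hi, close_up)
  ti <- band_bins(spectrum$freq, bounds$f_n, bounds$f_m, close_upper = TRUE)
  tot <- sum(spectrum$power[ti])
  if (tot <= 0) stop("zero total power in the analysis range")
  (sum(spectrum$power[bi]) / tot) * (length(ti) / length(bi))
}

#' Relative power of all bands for one window signal
#'
#' @param x broadband window signal (one channel).
#' @param fs sampling rate in Hz.
#' @param bands band definitions.
#' @param bounds analysis bounds.
#' @return Named numeric vector of per-band relative power.
#' @export
band_relative_powers <- function(x, fs, bands = eeg_bands(),
                                 bounds = spectral_bounds()) {
  sp <- power_spectrum(x, fs)
  out <- vapply(seq_len(nrow(bands)), function(i)
    relative_power(sp, bands[i, ], bounds), numeric(1))
  names(out) <- bands$band
  out
}

# per-band weights such that sum(RP * weight) == 1 exactly on the grid
band_weights <- function(n, fs, bands = eeg_bands(),
                         bounds = spectral_bounds()) {
  freq <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  ti <- band_bins(freq, bounds$f_n, bounds$f_m, close_upper = TRUE)
  w <- vapply(seq_len(nrow(bands)), function(i) {
    close_up <- abs(bands$f_hi[i] - bounds$f_m) < 1e-9
    length(band_bins(freq, bands$f_lo[i], bands$f_hi[i], close_up)) / length(ti)
  }, numeric(1))
  names(w) <- bands$band
  w
}

#' Fuzzy entropy of a window signal
#'
#' Irregularity measure comparing similarity of length-`m` and
#' length-`m + 1` subsequences. Each subsequence is baseline-corrected by
#' its own mean; pair similarity is `exp(-ln2 * (d/r)^2)` of their
#' Chebyshev distance `d`; FuzEn is the log-ratio of the average
#' similarity at the two dimensions. With the tolerance tied to the
#' window standard deviation (`r = k * sd(x)`) the value is invariant to
#' positive rescaling of the signal.
#'
#' @param x numeric window signal (band-filtered channel).
#' @param m embedding dimension (default 2).
#' @param k tolerance coefficient (default 0.2); ignored when `r` given.
#' @param r absolute tolerance; default `k * sd(x)`.
#' @return Non-negative scalar; lower values mean a more regular signal.
#' @export
fuzzy_entropy <- function(x, m = 2, k = 0.2, r = NULL) {
  n <- length(x)
  if (n <= m + 1L) stop("signal too short: need length > m + 1")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  if (is.null(r)) {
    stopifnot(k > 0, k < 1)
    r <- k * sd(x)
  }
  if (!(r > 0)) stop("constant signal: fuzzy entropy undefined (sd = 0)")
  fuzen_cpp(as.numeric(x), as.integer(m), r)
}

#' Analytic signal via the FFT
#'
#' @param x real numeric vector.
#' @return Complex vector whose argument is the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase lag index between two window signals
#'
#' Absolute mean signum of the instantaneous phase difference, with
#' phases from the FFT analytic signal. `sign(0)` contributes exactly 0.
#' A fraction of samples at each end is excluded from the average to
#' limit finite-window Hilbert edge distortion.
#'
#' @param x,y equal-length window signals (band-filtered).
#' @param trim fraction of samples dropped at each end (default 0.05).
#' @return PLI in `[0, 1]`; 0 for identical signals, 1 for a constant
#'   nonzero phase lag.
#' @export
pli <- function(x, y, trim = 0.05) {
  if (length(x) != length(y))
    stop("signals must have equal length")
  stopifnot(trim >= 0, trim < 0.5)
  dphi <- Arg(analytic_signal(x)) - Arg(analytic_signal(y))
  n <- length(dphi)
  drop <- floor(trim * n)
  keep <- (drop + 1L):(n - drop)
  # wrap to (-pi, pi]; the signum of the wrapped difference is what counts
  d <- dphi[keep]
  d <- atan2(sin(d), cos(d))
  abs(mean(sign(d)))
}

#' PLI connectivity matrix for one band window
#'
#' @param win channels x samples matrix (one band, one window).
#' @param trim edge trim fraction passed to [pli()].
#' @return Symmetric matrix with zero diagonal and entries in `[0, 1]`,
#'   with channel dimnames.
#' @export
pli_matrix <- function(win, trim = 0.05) {
  n_ch <- nrow(win)
  n <- ncol(win)
  drop <- floor(trim * n)
  keep <- (drop + 1L):(n - drop)
  ph <- matrix(NA_real_, nrow = n_ch, ncol = n)
  for (c in seq_len(n_ch)) ph[c, ] <- Arg(analytic_signal(win[c, ]))
  m <- matrix(0, n_ch, n_ch, dimnames = list(rownames(win), rownames(win)))
  for (a in seq_len(n_ch - 1L)) {
    for (b in (a + 1L):n_ch) {
      d <- ph[a, keep] - ph[b, keep]
      d <- atan2(sin(d), cos(d))
      v <- abs(mean(sign(d)))
      m[a, b] <- v
      m[b, a] <- v
    }
  }
  m
}

#' Canonical feature identities
#'
#' Enumerates the full feature space in its fixed canonical order:
#' family-major (RP, FuzEn, PLI), band-major within family (Delta through
#' Gamma), site order within band following the channel order; PLI sites
#' are unordered channel pairs `"A-B"` with A before B in channel order.
#' For 16 channels and 5 bands this yields 80 + 80 + 600 = 760 features.
#'
#' @param channels ordered channel labels.
#' @param bands band definitions.
#' @return data.frame with columns `family`, `band`, `site`, `name`.
#' @export
feature_keys <- function(channels = default_channels(),
                         bands = eeg_bands()) {
  bn <- bands$band
  pairs <- t(utils::combn(channels, 2))
  pair_site <- paste0(pairs[, 1], "-", pairs[, 2])
  rows <- list()
  for (fam in c("RP", "FuzEn")) {
    for (b in bn) {
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, band = b, site = channels,
                   stringsAsFactors = FALSE)
    }
  }
  for (b in bn) {
    rows[[length(rows) + 1L]] <-
      data.frame(family = "PLI", band = b, site = pair_site,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$name <- paste(out$family, out$band, out$site, sep = "_")
  out
}

# features of a single eeg_epochs object -> data.frame of rows
window_features <- function(ep, keys, fuzen_m = 2, fuzen_k = 0.2,
                            trim = 0.05, bands = eeg_bands(),
                            bounds = spectral_bounds(),
                            families = c("RP", "FuzEn", "PLI")) {
  n_ch <- length(ep$channels)
  bn <- dimnames(ep$bands)[[1]]
  vals <- matrix(NA_real_, nrow = ep$n_windows, ncol = nrow(keys),
                 dimnames = list(NULL, keys$name))
  dropped <- character(0)
  for (w in seq_len(ep$n_windows)) {
    ok <- TRUE
    if ("RP" %in% families) {
      for (c in seq_len(n_ch)) {
        x <- ep$broadband[w, c, ]
        if (sd(x) < .Machine$double.eps) { ok <- FALSE; break }
        rp <- band_relative_powers(x, ep$fs, bands, bounds)
        vals[w, paste("RP", names(rp), ep$channels[c], sep = "_")] <- rp
      }
    }
    if (ok && "FuzEn" %in% families) {
      for (b in bn) {
        for (c in seq_len(n_ch)) {
          x <- ep$bands[b, w, c, ]
          if (sd(x) < .Machine$double.eps) { ok <- FALSE; break }
          vals[w, paste("FuzEn", b, ep$channels[c], sep = "_")] <-
            fuzzy_entropy(x, m = fuzen_m, k = fuzen_k)
        }
        if (!ok) break
      }
    }
    if (ok && "PLI" %in% families) {
      for (b in bn) {
        pm <- pli_matrix(ep$bands[b, w, , ], trim = trim)
        # lower triangle column-major enumerates (a,b) pairs with a < b in
        # exactly the canonical combn() order (by symmetry of pm)
        ut <- pm[lower.tri(pm)]
        idx <- which(keys$family == "PLI" & keys$band == b)
        vals[w, idx] <- ut
      }
    }
    if (!ok) dropped <- c(dropped, sprintf("%s window %d: constant channel",
                                           ep$subject_id, w))
  }
  keep_cols <- keys$family %in% families
  df <- data.frame(subject_id = ep$subject_id, group = ep$group,
                   window_index = seq_len(ep$n_windows),
                   vals[, keys$name[keep_cols], drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  keep <- stats::complete.cases(df)
  attr(df, "dropped") <- dropped
  df[keep, , drop = FALSE]
}

#' Assemble the canonical feature table
#'
#' One row per (subject, window); feature columns in the fixed canonical
#' order of [feature_keys()]. RP is computed from the broadband window
#' periodogram; FuzEn and PLI from the band-filtered window signals.
#' Windows containing a constant channel are dropped (with a message)
#' rather than imputed.
#'
#' @param epochs list of `eeg_epochs` (or a single one).
#' @param fuzen_m,fuzen_k fuzzy entropy parameters.
#' @param trim PLI edge trim fraction.
#' @param bands,bounds spectral configuration.
#' @param families subset of `c("RP", "FuzEn", "PLI")` to compute;
#'   restricting families restricts the columns accordingly.
#' @return data.frame of class `eeg_features` with metadata columns
#'   `subject_id`, `group`, `window_index` and one column per feature;
#'   attribute `feature_keys` holds the key table.
#' @export
build_feature_table <- function(epochs, fuzen_m = 2, fuzen_k = 0.2,
                                trim = 0.05, bands = eeg_bands(),
                                bounds = spectral_bounds(),
                                families = c("RP", "FuzEn", "PLI")) {
  if (inherits(epochs, "eeg_epochs")) epochs <- list(epochs)
  families <- match.arg(families, several.ok = TRUE)
  ch <- epochs[[1]]$channels
  wl <- epochs[[1]]$window_length_s
  for (ep in epochs)
    if (!identical(ep$channels, ch) || !identical(ep$window_length_s, wl))
      stop("all epochs must share channel set and window length")
  keys <- feature_keys(ch, bands)
  parts <- lapply(epochs, window_features, keys = keys, fuzen_m = fuzen_m,
                  fuzen_k = fuzen_k, trim = trim, bands = bands,
                  bounds = bounds, families = families)
  dropped <- unlist(lapply(parts, attr, "dropped"))
  if (length(dropped))
    message("dropped ", length(dropped), " window(s): ",
            paste(dropped, collapse = "; "))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "feature_keys") <- keys[keys$family %in% families, ]
  attr(out, "dropped") <- dropped
  class(out) <- c("eeg_features", "data.frame")
  out
}

#' Extract features from a cohort
#'
#' Runs [preprocess_recording()] and [build_feature_table()] over every
#' recording of a cohort, one subject at a time.
#'
#' @param cohort an `eeg_cohort`.
#' @param window_length_s window length in seconds.
#' @inheritParams build_feature_table
#' @return An `eeg_features` data.frame.
#' @export
extract_features <- function(cohort, window_length_s = 4, fuzen_m = 2,
                             fuzen_k = 0.2, trim = 0.05,
                             bands = eeg_bands(),
                             bounds = spectral_bounds(),
                             families = c("RP", "FuzEn", "PLI")) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  parts <- lapply(cohort$recordings, function(rec) {
    ep <- preprocess_recording(rec, window_length_s, bands, bounds)
    build_feature_table(ep, fuzen_m, fuzen_k, trim, bands, bounds, families)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "feature_keys") <- attr(parts[[1]], "feature_keys")
  class(out) <- c("eeg_features", "data.frame")
  out
}

# metadata / feature-column helpers used across modules
meta_cols <- c("subject_id", "group", "window_index")

feature_cols <- function(table) setdiff(names(table), meta_cols)

#' @export
print.eeg_features <- function(x, ...) {
  fc <- feature_cols(x)
  cat(sprintf("<eeg_features> %d windows x %d features (%s)\n",
              nrow(x), length(fc),
              paste(sprintf("%s: %d", c("HC", "SCZ"),
                            c(sum(x$group == "HC"), sum(x$group == "SCZ"))),
                    collapse = ", ")))
  invisible(x)
}
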