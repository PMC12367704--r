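#' Canonical EEG frequency bands
#'
#' The five standard bands used throughout the package. Together they
#' partition the 0.5--45 Hz analysis range exactly: Delta 0.5--4, Theta
#' 4--8, Alpha 8--13, Beta 13--30, Gamma 30--45 Hz.
#'
#' @param names optional character vector to subset/reorder the default
#'   five bands.
#' @return A data.frame with columns `band`, `f_lo`, `f_hi` (Hz), ordered
#'   Delta through Gamma.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function(names = NULL) {
  b <- data.frame(
    band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    f_lo = c(0.5, 4, 8, 13, 30),
    f_hi = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, b$band)
    if (length(miss))
      stop("unknown band(s): ", paste(miss, collapse = ", "))
    b <- b[match(names, b$band), , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

#' Spectral analysis bounds
#'
#' Lower and upper frequency bounds of the broadband analysis range used
#' for filtering and as the denominator of relative power.
#'
#' @param f_n lower bound in Hz (default 0.5).
#' @param f_m upper bound in Hz (default 45).
#' @return A named list with elements `f_n` and `f_m`.
#' @export
spectral_bounds <- function(f_n = 0.5, f_m = 45) {
  stopifnot(is.numeric(f_n), is.numeric(f_m), length(f_n) == 1L,
            length(f_m) == 1L, f_n > 0, f_n < f_m)
  list(f_n = f_n, f_m = f_m)
}

#' Default 16-channel montage
#'
#' Channel labels of the 16-electrode 10--20 montage, in the fixed order
#' used for feature naming and pair enumeration.
#'
#' @return Character vector of 16 channel labels.
#' @export
default_channels <- function() {
  c("F3", "F4", "F7", "F8", "C3", "C4", "Cz", "T3", "T4", "T5", "T6",
    "P3", "P4", "Pz", "O1", "O2")
}

#' Channel-to-region assignment
#'
#' Maps each 10--20 channel label to a scalp region by its letter code:
#' frontal (F), central (C), temporal (T), parietal (P), occipital (O).
#'
#' @param channels channel labels (default the 16-channel montage).
#' @return Named character vector: region per channel.
#' @examples
#' channel_regions(c("F3", "Cz", "O2"))
#' @export
channel_regions <- function(channels = default_channels()) {
  reg <- c(F = "frontal", C = "central", T = "temporal",
           P = "parietal", O = "occipital")
  first <- substr(channels, 1, 1)
  bad <- !(first %in% names(reg))
  if (any(bad))
    stop("cannot assign region for channel(s): ",
         paste(channels[bad], collapse = ", "))
  structure(unname(reg[first]), names = channels)
}

# band center frequency, used for regularity oscillations and coupling lags
band_center <- function(band_row) (band_row$f_lo + band_row$f_hi) / 2

check_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands),
            all(c("band", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo))
    stop("invalid band definition: need 0 < f_lo < f_hi")
  if (any(bands$f_hi > fs / 2))
    stop("band upper edge exceeds the Nyquist frequency fs/2 = ", fs / 2)
  invisible(bands)
}
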