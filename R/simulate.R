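# Synthetic two-group EEG cohort generator.
#
# Each channel is a sum over the five bands of unit-variance band-limited
# filtered noise with fixed per-band base amplitudes (eyes-closed-like
# spectrum), scaled in the SCZ group by per-band power-shift factors.
# Phase coupling is planted per edge by blending a shared band-limited
# source into one channel and an integer-sample-delayed copy into the
# other; signal regularity is planted by replacing a variance fraction of
# the SCZ band signal with a narrowband sinusoid whose frequency is drawn
# per channel from the band interior (so unrelated channels do not lock).

# eyes-closed-like base amplitude per band (arbitrary units)
BASE_AMP <- c(Delta = 2.0, Theta = 1.5, Alpha = 2.5, Beta = 1.0, Gamma = 0.6)

#' Group-difference effect specification
#'
#' Describes how the simulated SCZ group differs from HC: per-band
#' multiplicative amplitude shifts (band power), per-band regularity gains
#' (fraction of band variance replaced by a narrowband oscillation, which
#' lowers fuzzy entropy), and phase-coupling edges with separate coupling
#' strengths per group.
#'
#' @param band_power_shift named numeric, one multiplicative amplitude
#'   factor per band applied to SCZ channels (>1 raises band power).
#' @param regularity_gain named numeric in `[0, 1)`, per band; variance
#'   fraction replaced by a deterministic oscillation in SCZ channels.
#' @param coupling_edges data.frame with columns `chan_i`, `chan_j`,
#'   `band`, `coupling_hc`, `coupling_scz` (each in `[0, 1)`) and
#'   `phase_lag` in radians (must not be 0 or pi: zero-lag and antiphase
#'   coupling are invisible to the phase lag index).
#' @param noise_sd scale of the independent broadband sensor noise added
#'   to every channel.
#' @return An object of class `effect_spec`.
#' @seealso [default_effects()], [neutral_effects()]
#' @export
effect_spec <- function(band_power_shift = rep(1, 5),
                        regularity_gain = rep(0, 5),
                        coupling_edges = NULL,
                        noise_sd = 0.3) {
  bands <- eeg_bands()$band
  nm <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) != length(bands))
        stop(what, " needs one value per band or band names")
      names(x) <- bands
    }
    miss <- setdiff(bands, names(x))
    x[miss] <- if (what == "band_power_shift") 1 else 0
    x[bands]
  }
  band_power_shift <- nm(band_power_shift, "band_power_shift")
  regularity_gain <- nm(regularity_gain, "regularity_gain")
  if (any(band_power_shift <= 0))
    stop("band power shift factors must be positive")
  if (any(regularity_gain < 0 | regularity_gain >= 1))
    stop("regularity gains must lie in [0, 1)")
  if (!is.null(coupling_edges)) {
    need <- c("chan_i", "chan_j", "band", "coupling_hc", "coupling_scz",
              "phase_lag")
    if (!all(need %in% names(coupling_edges)))
      stop("coupling_edges must have columns ", paste(need, collapse = ", "))
    cp <- c(coupling_edges$coupling_hc, coupling_edges$coupling_scz)
    if (any(cp < 0 | cp >= 1))
      stop("coupling strengths must lie in [0, 1)")
    lag <- coupling_edges$phase_lag %% (2 * pi)
    if (any(abs(lag) < 1e-6 | abs(lag - pi) < 1e-6))
      stop("phase_lag must differ from 0 and pi for PLI-detectable coupling")
    if (any(!coupling_edges$band %in% bands))
      stop("unknown band in coupling_edges")
  }
  structure(list(band_power_shift = band_power_shift,
                 regularity_gain = regularity_gain,
                 coupling_edges = coupling_edges,
                 noise_sd = noise_sd),
            class = "effect_spec")
}

#' Default planted group differences
#'
#' Effect directions follow the pattern reported for pediatric
#' schizophrenia: band power raised in delta/theta/beta and lowered in
#' alpha/gamma; signal regularity raised (entropy lowered) in all bands
#' but delta; phase coupling raised in theta/beta/gamma edges linking
#' frontal, central and parietal sites and lowered in right-sided alpha
#' edges toward parieto-occipital sites.
#'
#' @param strength scales the departure of every effect from neutral
#'   (1 = default magnitudes, 0 = neutral cohort).
#' @return An `effect_spec`.
#' @export
default_effects <- function(strength = 1) {
  s <- strength
  shift <- c(Delta = 1.3, Theta = 1.3, Alpha = 0.7, Beta = 1.3, Gamma = 0.75)
  edges <- data.frame(
    chan_i = c("F3", "F4", "F3", "F4", "C3", "C4", "F4", "T6"),
    chan_j = c("C3", "C4", "P3", "P4", "P3", "P4", "P4", "O2"),
    band   = c("Theta", "Theta", "Beta", "Beta", "Gamma", "Gamma",
               "Alpha", "Alpha"),
    coupling_hc  = c(rep(0.15, 6), 0.55, 0.55),
    coupling_scz = c(rep(0.55, 6), 0.05, 0.05),
    phase_lag = pi / 4,
    stringsAsFactors = FALSE
  )
  edges$coupling_scz <- edges$coupling_hc +
    s * (edges$coupling_scz - edges$coupling_hc)
  effect_spec(
    band_power_shift = 1 + s * (shift - 1),
    regularity_gain = c(Delta = 0, Theta = 0.3, Alpha = 0.3,
                        Beta = 0.3, Gamma = 0.3) * s,
    coupling_edges = edges,
    noise_sd = 0.3
  )
}

#' Neutral (null) effect specification
#'
#' All shifts at 1, all gains at 0, no coupling edges: both groups are
#' draws from the same distribution.
#'
#' @return An `effect_spec`.
#' @export
neutral_effects <- function() effect_spec()

#' Cohort configuration
#'
#' @param n_hc,n_scz number of subjects per group (>= 1).
#' @param fs sampling rate in Hz (must exceed 90 Hz so the 45-Hz analysis
#'   bound is below Nyquist).
#' @param duration_s recording length per subject in seconds;
#'   `duration_s * fs` must be an integer.
#' @param channels ordered channel labels (default 16-channel montage).
#' @param seed master random seed for the cohort.
#' @param effects an [effect_spec()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 39, n_scz = 45, fs = 128, duration_s = 60,
                          channels = default_channels(), seed = 1,
                          effects = default_effects()) {
  stopifnot(n_hc >= 1, n_scz >= 1, fs > 2 * 45,
            abs(duration_s * fs - round(duration_s * fs)) < 1e-9)
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!inherits(effects, "effect_spec")) stop("`effects` must be an effect_spec")
  ed <- effects$coupling_edges
  if (!is.null(ed)) {
    bad <- setdiff(c(ed$chan_i, ed$chan_j), channels)
    if (length(bad))
      stop("coupling_edges name unknown channel(s): ",
           paste(unique(bad), collapse = ", "))
    if (any(ed$chan_i == ed$chan_j))
      stop("coupling edges must join two distinct channels")
  }
  structure(list(n_hc = n_hc, n_scz = n_scz, fs = fs,
                 duration_s = duration_s, channels = channels,
                 seed = seed, effects = effects),
            class = "cohort_config")
}

# unit-variance band-limited noise, generated with the analysis filters;
# `pad` extra samples on each side absorb filter transients, `shift` > 0
# additionally returns a copy delayed by `shift` samples
band_noise <- function(n, f_lo, f_hi, fs, pad = 2 * fs, shift = 0L) {
  w <- rnorm(n + 2L * pad + shift)
  y <- bp_filter(w, f_lo, f_hi, fs)
  cur <- y[(pad + shift + 1L):(pad + shift + n)]
  s <- sd(cur)
  if (s < .Machine$double.eps) stop("degenerate band noise")
  if (shift > 0L) {
    lagged <- y[(pad + 1L):(pad + n)] / s   # lagged(t) = cur(t - shift)
    list(cur = cur / s, lagged = lagged)
  } else cur / s
}

#' Simulate one EEG recording
#'
#' Draws a single subject's multichannel recording under the group's
#' planted effects. See the package vignette for the generative model.
#'
#' @param config a [cohort_config()].
#' @param group `"HC"` or `"SCZ"`.
#' @param seed seed for this recording (defaults to the config seed).
#' @param subject_id subject identifier.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(config, group = c("HC", "SCZ"),
                               seed = config$seed, subject_id = "S1") {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  ef <- config$effects
  bands <- eeg_bands()
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  n_ch <- length(config$channels)
  set.seed(seed)

  x <- matrix(0, nrow = n_ch, ncol = n,
              dimnames = list(config$channels, NULL))
  for (b in seq_len(nrow(bands))) {
    bname <- bands$band[b]
    f_lo <- bands$f_lo[b]; f_hi <- bands$f_hi[b]
    e <- matrix(0, nrow = n_ch, ncol = n)
    for (c in seq_len(n_ch))
      e[c, ] <- band_noise(n, f_lo, f_hi, fs)

    ed <- ef$coupling_edges
    if (!is.null(ed)) {
      ed <- ed[ed$band == bname, , drop = FALSE]
      for (k in seq_len(nrow(ed))) {
        gamma <- if (group == "SCZ") ed$coupling_scz[k] else ed$coupling_hc[k]
        f_c <- (f_lo + f_hi) / 2
        lag <- max(1L, as.integer(round(ed$phase_lag[k] / (2 * pi * f_c) * fs)))
        src <- band_noise(n, f_lo, f_hi, fs, shift = lag)
        i <- match(ed$chan_i[k], config$channels)
        j <- match(ed$chan_j[k], config$channels)
        # blend preserves unit variance; channel j lags channel i
        x_mix <- sqrt(1 - gamma^2)
        e[i, ] <- x_mix * e[i, ] + gamma * src$cur
        e[j, ] <- x_mix * e[j, ] + gamma * src$lagged
      }
    }

    g <- ef$regularity_gain[[bname]]
    if (group == "SCZ" && g > 0) {
      # Regularity: concentrate the stochastic band energy toward the
      # lower band edge (slower, more predictable at the sample scale —
      # what fuzzy entropy actually responds to in band-limited signals)
      # and replace a variance fraction g with a deterministic tone.
      # The tone frequency is drawn per channel so unrelated channels do
      # not phase-lock; re-filtering (not regenerating) the band signal
      # preserves planted coupling within the retained sub-band.
      tt <- seq_len(n) / fs
      width <- f_hi - f_lo
      hi <- f_lo + max((1 - g)^2, 0.1) * width
      q <- 0.3 * g  # tone variance share capped: near-frequency tones on
                    # different channels would otherwise phase-lock spuriously
      for (c in seq_len(n_ch)) {
        slow <- bp_filter(e[c, ], f_lo, hi, fs)
        s <- sd(slow)
        if (s > .Machine$double.eps) slow <- slow / s
        f_osc <- runif(1, f_lo + 0.1 * (hi - f_lo), hi - 0.1 * (hi - f_lo))
        phi <- runif(1, 0, 2 * pi)
        osc <- sqrt(2) * sin(2 * pi * f_osc * tt + phi)
        e[c, ] <- sqrt(1 - q) * slow + sqrt(q) * osc
      }
    }

    amp <- BASE_AMP[[bname]] *
      (if (group == "SCZ") ef$band_power_shift[[bname]] else 1)
    x <- x + amp * e
  }
  x <- x + ef$noise_sd * matrix(rnorm(n_ch * n), nrow = n_ch)
  eeg_recording(x, fs = fs, channels = config$channels,
                subject_id = subject_id, group = group)
}

#' Simulate a two-group cohort
#'
#' Generates `n_hc + n_scz` recordings with per-subject sub-seeds derived
#' deterministically from the master seed, plus a manifest.
#'
#' @param config a [cohort_config()].
#' @return An object of class `eeg_cohort`: list with `recordings` (list
#'   of `eeg_recording`) and `manifest` (data.frame: subject_id, group,
#'   seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_tot <- config$n_hc + config$n_scz
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  groups <- c(rep("HC", config$n_hc), rep("SCZ", config$n_scz))
  ids <- sprintf("%s%02d", ifelse(groups == "HC", "h", "s"),
                 c(seq_len(config$n_hc), seq_len(config$n_scz)))
  recs <- vector("list", n_tot)
  for (i in seq_len(n_tot))
    recs[[i]] <- simulate_recording(config, groups[i], seed = sub_seeds[i],
                                    subject_id = ids[i])
  names(recs) <- ids
  structure(list(recordings = recs,
                 manifest = data.frame(subject_id = ids, group = groups,
                                       seed = sub_seeds,
                                       stringsAsFactors = FALSE),
                 config = config),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d HC + %d SCZ subjects, %g s @ %g Hz, %d channels\n",
              x$config$n_hc, x$config$n_scz, x$config$duration_s,
              x$config$fs, length(x$config$channels)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One text matrix file per subject plus `manifest.csv`.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, paste0(rec$subject_id, ".csv")))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing per-subject files and `manifest.csv`.
#' @param fs sampling rate of the stored recordings.
#' @param channels channel labels.
#' @return An `eeg_cohort` (without a generating config).
#' @export
read_cohort <- function(dir, fs = 128, channels = default_channels()) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(man)), function(i)
    read_recording(file.path(dir, paste0(man$subject_id[i], ".csv")),
                   fs = fs, channels = channels,
                   subject_id = man$subject_id[i], group = man$group[i]))
  names(recs) <- man$subject_id
  structure(list(recordings = recs, manifest = man, config = NULL),
            class = "eeg_cohort")
}
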