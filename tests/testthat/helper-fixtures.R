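# Fixture builders shared across test files.

# small cohort with configurable effects
tiny_cohort <- function(n_per_group = 4, duration_s = 12, seed = 11,
                        effects = default_effects()) {
  simulate_cohort(cohort_config(n_hc = n_per_group, n_scz = n_per_group,
                                duration_s = duration_s, seed = seed,
                                effects = effects))
}

# feature table of pure noise with optional informative columns whose
# group means differ by `delta` (in sd units)
noise_table <- function(n_rows = 200, n_feat = 20, seed = 1,
                        informative = integer(0), delta = 2,
                        windows_per_subject = 5) {
  set.seed(seed)
  grp <- rep(c("HC", "SCZ"), each = n_rows / 2)
  x <- matrix(rnorm(n_rows * n_feat), n_rows, n_feat)
  for (j in informative)
    x[grp == "SCZ", j] <- x[grp == "SCZ", j] + delta
  colnames(x) <- sprintf("f%03d", seq_len(n_feat))
  n_subj <- ceiling(n_rows / windows_per_subject)
  df <- data.frame(
    subject_id = sprintf("x%03d", rep(seq_len(n_subj),
                                      each = windows_per_subject)[seq_len(n_rows)]),
    group = grp,
    window_index = rep(seq_len(windows_per_subject), n_subj)[seq_len(n_rows)],
    x, check.names = FALSE, stringsAsFactors = FALSE
  )
  class(df) <- c("eeg_features", "data.frame")
  df
}

# unit-variance band-limited noise window (independent of package internals)
band_noise_window <- function(n = 512, f_lo = 8, f_hi = 13, fs = 128) {
  w <- rnorm(n + 1024)
  bt <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bt, w)[513:(512 + n)]
  y / sd(y)
}
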