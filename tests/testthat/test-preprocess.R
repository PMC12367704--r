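test_that("text recordings round-trip and malformed files are rejected", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(16 * 256), 16), fs = 128,
                       channels = default_channels(), subject_id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, fs = 128)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  expect_equal(back$channels, default_channels())

  # wrong column count
  utils::write.table(matrix(rnorm(20 * 15), 20), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_recording(path, fs = 128), "15")
  # non-numeric entries
  writeLines(c(paste(default_channels(), collapse = ","),
               paste(rep("a", 16), collapse = ",")), path)
  expect_error(read_recording(path, fs = 128), "non-numeric")
})

test_that("average reference zeroes the channel mean at every sample", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(16 * 128 * 6), 16), fs = 128,
                       channels = default_channels())
  out <- bandpass_and_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9 * stats::sd(out$data))
})

test_that("broadband filter attenuates the stopband and passes the passband", {
  fs <- 128  # 60 Hz lies above the 45-Hz analysis bound at this rate
  t <- seq_len(8 * fs) / fs
  mk <- function(f) {
    s <- sin(2 * pi * f * t)
    # opposite-polarity pair keeps the signal invariant to average reference
    eeg_recording(rbind(A = s, B = -s), fs = fs, channels = c("A", "B"))
  }
  trim <- (2 * fs):(6 * fs)  # evaluate away from filter edges
  out60 <- bandpass_and_reference(mk(60))$data[1, trim]
  expect_lt(sqrt(mean(out60^2)), 0.01 * sqrt(0.5))
  out10 <- bandpass_and_reference(mk(10))$data[1, trim]
  expect_lt(abs(sqrt(mean(out10^2)) - sqrt(0.5)) / sqrt(0.5), 0.05)
})

test_that("band decomposition isolates a 10-Hz tone into the alpha band", {
  fs <- 128
  t <- seq_len(10 * fs) / fs
  s <- sin(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(A = s, B = -s), fs = fs, channels = c("A", "B"))
  bd <- band_decompose(rec)
  trim <- (2 * fs):(8 * fs)
  en <- vapply(bd, function(m) sum(m[1, trim]^2), numeric(1))
  expect_gt(en[["Alpha"]] / sum(en), 0.95)
})

test_that("white-noise band variance scales with bandwidth", {
  set.seed(4)
  fs <- 128
  rec <- eeg_recording(matrix(rnorm(2 * 60 * fs), 2), fs = fs,
                       channels = c("A", "B"))
  bd <- band_decompose(rec)
  b <- eeg_bands()
  v <- vapply(bd, function(m) var(m[1, ]), numeric(1))
  width <- b$f_hi - b$f_lo
  ratio <- (v / sum(v)) / (width / sum(width))
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("zero input yields zero band signals and bad bands error", {
  rec <- eeg_recording(matrix(0, 2, 512) + 0, fs = 128, channels = c("A", "B"))
  bd <- band_decompose(rec)
  expect_true(all(vapply(bd, function(m) max(abs(m)), numeric(1)) < 1e-12))
  expect_error(band_decompose(rec, data.frame(band = "X", f_lo = 10, f_hi = 70)),
               "Nyquist")
})

test_that("windowing counts, shapes and reconstruction are exact", {
  set.seed(5)
  mkrec <- function(secs) eeg_recording(matrix(rnorm(3 * secs * 128), 3),
                                        fs = 128, channels = c("A", "B", "C"))
  rec <- mkrec(60)
  bd <- band_decompose(rec)
  ep4 <- segment_windows(rec, bd, 4)
  expect_equal(ep4$n_windows, 15L)
  expect_equal(dim(ep4$broadband), c(15L, 3L, 512L))
  expect_equal(dim(ep4$bands), c(5L, 15L, 3L, 512L))
  # concatenating windows reconstructs the first 15*512 samples exactly
  rebuilt <- do.call(cbind, lapply(seq_len(15), function(w) ep4$broadband[w, , ]))
  expect_identical(rebuilt, unname(rec$data[, 1:(15 * 512)]))
  expect_equal(segment_windows(rec, bd, 6)$n_windows, 10L)

  rec61 <- mkrec(61)
  expect_equal(segment_windows(rec61, band_decompose(rec61), 4)$n_windows, 15L)
  rec2 <- mkrec(2)
  expect_error(segment_windows(rec2, band_decompose(rec2), 4), "shorter")
})

test_that("average reference survives band decomposition (linearity)", {
  set.seed(6)
  rec <- eeg_recording(matrix(rnorm(16 * 128 * 8), 16), fs = 128,
                       channels = default_channels())
  refd <- bandpass_and_reference(rec)
  bd <- band_decompose(refd)
  for (m in bd)
    expect_lt(max(abs(colMeans(m))), 1e-6 * max(stats::sd(m), 1e-12))
})

test_that("filtering an already band-limited signal is near-idempotent", {
  set.seed(7)
  fs <- 128
  # probe occupies the band interior, away from the filter's rolloff edges
  y <- band_noise_window(n = 20 * fs, f_lo = 9, f_hi = 12, fs = fs)
  rec <- eeg_recording(rbind(A = y, B = -y), fs = fs, channels = c("A", "B"))
  again <- band_decompose(rec)[["Alpha"]][1, ]
  trim <- (3 * fs):(17 * fs)
  rms0 <- sqrt(mean(y[trim]^2))
  rms1 <- sqrt(mean(again[trim]^2))
  expect_lt(abs(rms1 - rms0) / rms0, 0.05)
})
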