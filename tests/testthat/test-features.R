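test_that("periodogram concentrates an on-bin tone and satisfies Parseval", {
  fs <- 128; n <- 512
  x <- sin(2 * pi * 10 * seq_len(n) / fs)
  sp <- power_spectrum(x, fs)
  i10 <- which.min(abs(sp$freq - 10))
  expect_gt(sum(sp$power[(i10 - 1):(i10 + 1)]) / sum(sp$power), 0.99)

  expect_true(all(power_spectrum(rep(0, 64), fs)$power == 0))

  for (seed in 1:5) {
    set.seed(seed)
    z <- rnorm(sample(c(256, 511, 512), 1))
    sp <- power_spectrum(z, fs)
    expect_lt(abs(sum(sp$power) - mean(z^2)) / mean(z^2), 1e-9)
  }
  expect_error(power_spectrum(numeric(0), fs), "at least 2")
})

test_that("relative power is 1 per band for a flat spectrum", {
  n <- 512; fs <- 128
  freq <- (0:(n / 2)) * fs / n
  flat <- list(freq = freq, power = rep(1, length(freq)))
  b <- eeg_bands()
  for (i in seq_len(nrow(b)))
    expect_equal(relative_power(flat, b[i, ]), 1, tolerance = 1e-12)
})

test_that("a pure alpha tone yields RP near the bandwidth ratio, others near 0", {
  fs <- 128
  x <- sin(2 * pi * 10 * seq_len(512) / fs)
  rp <- band_relative_powers(x, fs)
  # (45 - 0.5) / (13 - 8) = 8.9 up to the discrete-grid bandwidth
  expect_equal(unname(rp[["Alpha"]]), 8.9, tolerance = 0.02)
  expect_true(all(rp[c("Delta", "Theta", "Beta", "Gamma")] < 0.01))
})

test_that("bandwidth-weighted RP sums to 1 on arbitrary windows", {
  w <- eegmarkers:::band_weights(512, 128)
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(512)
    rp <- band_relative_powers(x, 128)
    expect_lt(abs(sum(rp * w) - 1), 1e-9)
  }
  # and on a window length whose grid does not align with band edges
  w1 <- eegmarkers:::band_weights(128, 128)
  x <- rnorm(128)
  expect_lt(abs(sum(band_relative_powers(x, 128) * w1) - 1), 1e-9)
})

test_that("fuzzy entropy is scale invariant and ranks noise above a tone", {
  set.seed(8)
  x <- rnorm(512)
  expect_identical(fuzzy_entropy(x), fuzzy_entropy(5 * x))
  tone <- sin(2 * pi * 10 * seq_len(512) / 128)
  expect_gt(fuzzy_entropy(x), fuzzy_entropy(tone))
  expect_gte(fuzzy_entropy(x), 0)
  expect_error(fuzzy_entropy(rep(1, 100)), "constant")
  expect_error(fuzzy_entropy(c(1, 2, 3), m = 2), "short")
})

test_that("optimized fuzzy entropy matches the brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- if (seed %% 2) rnorm(300) else band_noise_window(300)
    expect_lt(abs(fuzzy_entropy(x) - fuzen_oracle(x)), 1e-10)
  }
})

test_that("PLI analytic cases: identical signals 0, constant lag 1", {
  x <- band_noise_window(512)
  expect_identical(pli(x, x), 0)
  t <- seq_len(512) / 128
  s1 <- sin(2 * pi * 10 * t)
  s2 <- sin(2 * pi * 10 * t - pi / 4)
  expect_equal(pli(s1, s2, trim = 0.05), 1)
  expect_equal(pli(s1, s2, trim = 0), 1)
  expect_error(pli(s1, s2[-1]), "equal length")
})

test_that("PLI is symmetric, amplitude invariant and bounded", {
  set.seed(9)
  for (i in 1:5) {
    x <- band_noise_window(512)
    y <- band_noise_window(512)
    v <- pli(x, y)
    expect_identical(v, pli(y, x))
    expect_identical(v, pli(3.7 * x, y))
    expect_true(v >= 0 && v <= 1)
    expect_lt(v, 0.35)   # independent windows: finite-sample null level
  }
})

test_that("PLI agrees with the direct sign-loop oracle", {
  set.seed(10)
  for (i in 1:6) {
    x <- band_noise_window(400, f_lo = 13, f_hi = 30)
    y <- band_noise_window(400, f_lo = 13, f_hi = 30)
    expect_lt(abs(pli(x, y) - pli_oracle(x, y)), 1e-12)
  }
})

test_that("the PLI matrix is symmetric with zero diagonal in canonical order", {
  set.seed(11)
  win <- matrix(rnorm(16 * 256), 16,
                dimnames = list(default_channels(), NULL))
  m <- pli_matrix(win)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(sum(lower.tri(m)), 120L)
  # flattening order matches the canonical pair enumeration
  flat <- m[lower.tri(m)]
  pairs <- t(utils::combn(default_channels(), 2))
  k <- c(1, 16, 120)
  for (i in k)
    expect_identical(flat[i], m[pairs[i, 1], pairs[i, 2]])
})

test_that("feature keys enumerate 760 features in the frozen canonical order", {
  keys <- feature_keys()
  expect_equal(nrow(keys), 760L)
  expect_equal(as.vector(table(keys$family)[c("RP", "FuzEn", "PLI")]),
               c(80L, 80L, 600L))
  # golden positions of the canonical ordering
  expect_identical(keys$name[1], "RP_Delta_F3")
  expect_identical(keys$name[17], "RP_Theta_F3")
  expect_identical(keys$name[80], "RP_Gamma_O2")
  expect_identical(keys$name[81], "FuzEn_Delta_F3")
  expect_identical(keys$name[161], "PLI_Delta_F3-F4")
  expect_identical(keys$name[760], "PLI_Gamma_O1-O2")
})

test_that("the feature table has canonical shape and flags degenerate windows", {
  coh <- tiny_cohort(n_per_group = 1, duration_s = 4, seed = 13)
  ep <- preprocess_recording(coh$recordings[[1]], 4)
  tab <- build_feature_table(ep)
  expect_s3_class(tab, "eeg_features")
  expect_equal(nrow(tab), 1L)
  expect_equal(ncol(tab), 763L)
  expect_identical(names(tab)[1:3], c("subject_id", "group", "window_index"))
  expect_identical(names(tab)[-(1:3)], feature_keys()$name)
  expect_true(!anyNA(tab))

  # a constant channel drops the whole row, with a message
  ep$bands[2, 1, 3, ] <- 0
  expect_message(tab0 <- build_feature_table(ep), "constant channel")
  expect_equal(nrow(tab0), 0L)
})
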