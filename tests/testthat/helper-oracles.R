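# Independent brute-force oracles, written directly from the defining
# equations and kept free of the package's optimized code paths.

# Fuzzy entropy: direct double loop over subsequence pairs. Subsequences
# at dimension mm are baseline-corrected by their own mean; membership is
# exp(-ln2 (d/r)^2) of the Chebyshev distance; both dimensions use the
# first N - m subsequences so pair counts match.
fuzen_oracle <- function(x, m = 2, k = 0.2, r = k * sd(x)) {
  N <- length(x)
  n <- N - m
  phi <- function(mm) {
    X <- matrix(NA_real_, n, mm)
    for (i in seq_len(n)) {
      seg <- x[i:(i + mm - 1)]
      X[i, ] <- seg - mean(seg)
    }
    tot <- 0
    for (i in seq_len(n)) {
      d <- rep(0, n)
      for (kk in seq_len(mm)) d <- pmax(d, abs(X[, kk] - X[i, kk]))
      memb <- exp(-log(2) * (d / r)^2)
      tot <- tot + (sum(memb) - 1) / (n - 1)   # drop the self-pair (d=0)
    }
    tot / n
  }
  log(phi(m)) - log(phi(m + 1))
}

# PLI: explicit sample loop over the signum of the wrapped instantaneous
# phase difference, with its own FFT analytic-signal construction.
hilbert_oracle <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  stats::fft(X * h, inverse = TRUE) / n
}

pli_oracle <- function(x, y, trim = 0.05) {
  px <- Arg(hilbert_oracle(x))
  py <- Arg(hilbert_oracle(y))
  n <- length(px)
  drop <- floor(trim * n)
  s <- 0
  cnt <- 0
  for (t in (drop + 1):(n - drop)) {
    d <- px[t] - py[t]
    while (d > pi) d <- d - 2 * pi
    while (d <= -pi) d <- d + 2 * pi
    s <- s + sign(d)
    cnt <- cnt + 1
  }
  abs(s / cnt)
}
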