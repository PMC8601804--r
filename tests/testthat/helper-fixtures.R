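# Shared fixtures: tiny signals and independent brute-force oracles.

make_tone <- function(freq, sr = 16000, n = 4096, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1L) / sr + phase)
}

# silence + tone burst + silence, in samples
make_burst_clip <- function(freq = 400, sr = 16000, silence_s = 0.5, burst_s = 1) {
  sil <- numeric(round(silence_s * sr))
  burst <- make_tone(freq, sr, round(burst_s * sr))
  audio_clip(c(sil, burst, sil), sr)
}

# literal O(N^2) DFT magnitude oracle for bins 0..N/2
dft_magnitude_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n %/% 2)
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (seq_len(n) - 1L) / n)))
  }, numeric(1L))
}

# literal two-pass bandwidth oracle (0-based bins, power weights)
bandwidth_oracle <- function(s) {
  p <- s^2
  i <- seq_along(s) - 1
  fc <- sum(i * p) / sum(p)
  sum(p * (i - fc)^2) / sum(p)
}

# textbook MFCC oracle: explicit filterbank rows and explicit DCT sums
mfcc_oracle <- function(spectrum, sr, n_mels = 26, p = 12) {
  nyq <- sr / 2
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(0, mel(nyq), length.out = n_mels + 2))
  nb <- length(spectrum)
  binf <- (seq_len(nb) - 1) * nyq / (nb - 1)
  e <- numeric(n_mels)
  for (m in seq_len(n_mels)) {
    wgt <- numeric(nb)
    for (b in seq_len(nb)) {
      f <- binf[b]
      if (f >= pts[m] && f <= pts[m + 1]) {
        wgt[b] <- (f - pts[m]) / (pts[m + 1] - pts[m])
      } else if (f > pts[m + 1] && f <= pts[m + 2]) {
        wgt[b] <- (pts[m + 2] - f) / (pts[m + 2] - pts[m + 1])
      }
    }
    e[m] <- log(max(sum(wgt * spectrum^2), 1e-10))
  }
  out <- numeric(p)
  for (k in seq_len(p)) {
    acc <- 0
    for (m in seq_len(n_mels)) acc <- acc + e[m] * cos(pi * k * (m - 0.5) / n_mels)
    out[k] <- sqrt(2 / n_mels) * acc
  }
  out
}

# AR(p) sample path x[n] = sum a_k x[n-k] + e[n]
make_ar <- function(a, n, sd = 1, burn = 500) {
  e <- rnorm(n + burn, sd = sd)
  x <- as.numeric(stats::filter(e, a, method = "recursive"))
  x[(burn + 1):(burn + n)]
}

# white noise through cascaded two-pole resonators
resonate <- function(x, freqs, sr, r = 0.98) {
  for (f in freqs) {
    x <- as.numeric(stats::filter(x, c(2 * r * cos(2 * pi * f / sr), -r^2),
                                  method = "recursive"))
  }
  x
}

# Gaussian blob classification fixture; informative dims are class centers
make_blobs <- function(n_per_class, centers, sd = 0.5, labels = letters[seq_along(centers)]) {
  rows <- mapply(function(ctr, lab) {
    m <- sapply(ctr, function(c0) rnorm(n_per_class, c0, sd))
    df <- as.data.frame(m)
    names(df) <- paste0("x", seq_along(ctr))
    df$label <- lab
    df
  }, centers, labels, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}
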