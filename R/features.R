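#' @name frame-features
#' @title Time-domain frame features
#'
#' @description Scalar features of a single time-domain frame:
#' \code{frame_magnitude} is the sum of absolute amplitudes,
#' \code{frame_average} the arithmetic mean of the signed samples,
#' \code{frame_variance} the population variance (divisor N), and
#' \code{zero_crossing_rate} the fraction of adjacent sample pairs whose
#' signs differ (zeros inherit the preceding sign).
#'
#' @param frame Numeric sample vector.
#' @return A single numeric value.
NULL

#' @rdname frame-features
#' @export
frame_magnitude <- function(frame) sum(abs(frame))

#' @rdname frame-features
#' @export
frame_average <- function(frame) mean(frame)

#' @rdname frame-features
#' @export
frame_variance <- function(frame) mean((frame - mean(frame))^2)

#' @rdname frame-features
#' @export
zero_crossing_rate <- function(frame) {
  n <- length(frame)
  if (n < 2L) return(0)
  sg <- sign(frame)
  for (i in 2L:n) if (sg[i] == 0) sg[i] <- sg[i - 1L]
  sum(sg[-1L] != sg[-n]) / (n - 1L)
}

#' Spectral bandwidth about the power-weighted centroid
#'
#' The squared-magnitude-weighted spread (in squared bin units) about the
#' power-weighted spectral centroid
#' \eqn{FC = \sum i |S(i)|^2 / \sum |S(i)|^2}:
#' \eqn{FB = \sum |S(i)|^2 (i - FC)^2 / \sum |S(i)|^2}. Bin indices are
#' 0-based; no square root is taken.
#'
#' @param spectrum Non-negative magnitude spectrum (one frame).
#' @return Bandwidth in bin^2; 0 (with a warning) for an all-zero spectrum.
#' @export
spectral_bandwidth <- function(spectrum) {
  p <- spectrum^2
  tot <- sum(p)
  if (tot == 0) {
    warning("spectral_bandwidth: all-zero spectrum, returning 0")
    return(0)
  }
  i <- seq_along(spectrum) - 1L
  fc <- sum(i * p) / tot
  sum(p * (i - fc)^2) / tot
}

#' Default logarithmically spaced subbands
#'
#' Splits the magnitude-spectrum bins \code{0..n_bins-1} into
#' \code{n_subbands} octave-style bands whose upper edges are the Nyquist
#' frequency divided by successive powers of 4 (at 4 bands and 44.1 kHz:
#' 0–689, 689–2756, 2756–11025, 11025–22050 Hz).
#'
#' @param n_bins Number of spectrum bins (N/2 + 1).
#' @param n_subbands Number of bands (default 4).
#' @return List of integer bin-index vectors (1-based into the spectrum).
#' @export
default_subbands <- function(n_bins, n_subbands = 4L) {
  fracs <- if (n_subbands > 1L) {
    c(0, 0.5 / 4^((n_subbands - 2L):0L), 1)
  } else {
    c(0, 1)
  }
  edges <- unique(pmax(1L, pmin(n_bins, round(fracs * n_bins))))
  edges[1L] <- 0L
  lapply(seq_len(length(edges) - 1L), function(k) (edges[k] + 1L):edges[k + 1L])
}

#' Spectral peak and valley features per subband
#'
#' Within each subband the magnitudes are sorted in descending order; the
#' peak feature is the natural log of the mean of the top
#' \code{ceiling(alpha * n)} magnitudes and the valley feature the log of
#' the mean of the bottom \code{ceiling(alpha * n)} magnitudes. Logs are
#' floored at \code{log(1e-10)}.
#'
#' @param spectrum Magnitude spectrum (one frame).
#' @param subbands List of bin-index vectors partitioning the spectrum;
#'   defaults to [default_subbands()].
#' @param alpha Fraction of each subband entering each mean (default 0.2).
#' @return List with numeric vectors \code{peak} and \code{valley}, one
#'   entry per subband.
#' @export
peak_valley <- function(spectrum, subbands = default_subbands(length(spectrum)),
                        alpha = 0.2) {
  stopifnot(alpha > 0, alpha <= 1)
  eps <- 1e-10
  res <- vapply(subbands, function(idx) {
    if (length(idx) == 0L) stop("peak_valley: empty subband")
    s <- sort(spectrum[idx], decreasing = TRUE)
    k <- ceiling(alpha * length(s))
    c(log(max(mean(s[seq_len(k)]), eps)),
      log(max(mean(rev(s)[seq_len(k)]), eps)))
  }, numeric(2L))
  list(peak = res[1L, ], valley = res[2L, ])
}

#' Pitch by normalized autocorrelation
#'
#' Estimates the fundamental frequency of a quasi-periodic segment as the
#' sample rate over the lag maximizing the normalized autocorrelation
#' \eqn{r(\ell)/r(0)} within the lag band corresponding to
#' \code{[f0_min, f0_max]}. The integer-lag peak is refined by parabolic
#' interpolation over its two neighbours. If the peak value falls below
#' \code{voicing_threshold}, the segment is declared unvoiced and 0 is
#' returned.
#'
#' @param segment Numeric sample sequence (at least two periods of
#'   \code{f0_min}).
#' @param sample_rate Hz.
#' @param f0_min,f0_max Search band in Hz (defaults 250 and 600, the neonate
#'   cry band).
#' @param voicing_threshold Minimum normalized autocorrelation of a voiced
#'   segment (default 0.3).
#' @return Estimated F0 in Hz, or 0 for unvoiced segments.
#' @export
pitch_autocorr <- function(segment, sample_rate, f0_min = 250, f0_max = 600,
                           voicing_threshold = 0.3) {
  n <- length(segment)
  lag_max <- ceiling(sample_rate / f0_min)
  lag_min <- max(2L, floor(sample_rate / f0_max))
  if (n < 2L * lag_max) {
    stop(sprintf("pitch_autocorr: segment too short (%d samples < 2 periods of %g Hz)",
                 n, f0_min))
  }
  x <- segment - mean(segment)
  r0 <- sum(x^2)
  if (r0 == 0) return(0)
  lags <- (lag_min - 1L):(lag_max + 1L)
  r <- vapply(lags, function(l) sum(x[1:(n - l)] * x[(l + 1L):n]), numeric(1L))
  inner <- 2L:(length(lags) - 1L)
  best <- inner[which.max(r[inner])]
  if (r[best] / r0 < voicing_threshold) return(0)
  a <- r[best - 1L]; b <- r[best]; cc <- r[best + 1L]
  denom <- a - 2 * b + cc
  delta <- if (denom != 0) 0.5 * (a - cc) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  sample_rate / (lags[best] + delta)
}

#' Levinson-Durbin solution of the LPC normal equations
#'
#' @param r Autocorrelation sequence \code{r[0..p]} (length p+1).
#' @param p Prediction order.
#' @return Prediction coefficients \code{a_1..a_p} of the model
#'   \eqn{x[n] \approx \sum_k a_k x[n-k]}.
#' @keywords internal
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  e <- r[1L]
  if (e <= 0) return(rep(0, p))
  for (m in seq_len(p)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc - sum(a[seq_len(m - 1L)] * r[m:2L])
    k <- acc / e
    a_new <- a
    a_new[m] <- k
    if (m > 1L) {
      a_new[seq_len(m - 1L)] <- a[seq_len(m - 1L)] - k * a[(m - 1L):1L]
    }
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  a
}

lpc_fit <- function(frame, order, window = TRUE) {
  x <- if (window) frame * hamming_window(length(frame)) else frame
  r <- vapply(0:order, function(l) {
    sum(x[1:(length(x) - l)] * x[(l + 1L):length(x)])
  }, numeric(1L))
  if (r[1L] <= 0) return(NULL)
  levinson_durbin(r, order)
}

#' Formant frequencies by LPC root-finding
#'
#' Fits an all-pole (LPC) model by the autocorrelation method and converts
#' the complex roots of the prediction polynomial with positive imaginary
#' part and bandwidth below \code{bw_max} into resonance frequencies
#' \eqn{f = \mathrm{arg}(z) \cdot f_s / 2\pi}. The lowest
#' \code{n_formants} frequencies are returned in ascending order, padded
#' with zeros when fewer are found.
#'
#' @param frame Time-domain frame.
#' @param sample_rate Hz.
#' @param lpc_order LPC order (default 18, suited to wideband audio).
#' @param n_formants Number of formants returned (default 6).
#' @param bw_max Maximum formant bandwidth in Hz (default 700).
#' @return Numeric vector \code{F1..Fn} in Hz (zeros when absent).
#' @export
formants_lpc <- function(frame, sample_rate, lpc_order = 18L, n_formants = 6L,
                         bw_max = 700) {
  a <- lpc_fit(frame, lpc_order)
  if (is.null(a)) {
    warning("formants_lpc: degenerate (zero-energy) frame, returning zeros")
    return(numeric(n_formants))
  }
  # roots of z^p - a1 z^(p-1) - ... - ap
  z <- polyroot(c(-rev(a), 1))
  freq <- Arg(z) * sample_rate / (2 * pi)
  bw <- -log(pmax(Mod(z), 1e-12)) * sample_rate / pi
  keep <- Arg(z) > 0 & bw < bw_max & freq > 50 & freq < sample_rate / 2 - 50
  f <- sort(freq[keep])
  out <- numeric(n_formants)
  out[seq_len(min(n_formants, length(f)))] <- f[seq_len(min(n_formants, length(f)))]
  out
}

#' Linear-prediction cepstral coefficients
#'
#' LPC coefficients \code{a_1..a_p} are obtained by the autocorrelation
#' (Levinson-Durbin) method and converted to cepstral coefficients by the
#' recursion \eqn{c_m = a_m + \sum_{k=1}^{m-1} (k/m) c_k a_{m-k}}.
#'
#' @param frame Time-domain frame.
#' @param p Order (number of coefficients, default 12).
#' @return Numeric vector \code{LPCC_1..LPCC_p} (zeros, with a warning, for
#'   a zero-energy frame).
#' @export
lpcc <- function(frame, p = 12L) {
  a <- lpc_fit(frame, p)
  if (is.null(a)) {
    warning("lpcc: degenerate (zero-energy) frame, returning zeros")
    return(numeric(p))
  }
  lpc_to_cepstrum(a, p)
}

#' @rdname lpcc
#' @param a LPC prediction coefficients \code{a_1..a_p}.
#' @export
lpc_to_cepstrum <- function(a, p = length(a)) {
  c_ <- numeric(p)
  for (m in seq_len(p)) {
    acc <- if (m <= length(a)) a[m] else 0
    if (m > 1L) {
      k <- seq_len(m - 1L)
      am <- ifelse(m - k <= length(a), a[pmax(m - k, 1L)], 0)
      acc <- acc + sum((k / m) * c_[k] * am)
    }
    c_[m] <- acc
  }
  c_
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' HTK-convention filterbank of \code{n_mels} triangular filters spanning
#' 0 Hz to Nyquist, evaluated at the \code{n_bins} FFT bin frequencies.
#'
#' @param n_bins Number of spectrum bins (N/2 + 1).
#' @param sample_rate Hz.
#' @param n_mels Number of filters.
#' @return \code{n_mels x n_bins} weight matrix.
#' @export
mel_filterbank <- function(n_bins, sample_rate, n_mels = 26L) {
  nyq <- sample_rate / 2
  mel_pts <- seq(0, hz_to_mel(nyq), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_f <- (seq_len(n_bins) - 1L) * nyq / (n_bins - 1L)
  fb <- matrix(0, nrow = n_mels, ncol = n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_f - lo) / (ctr - lo)
    down <- (hi - bin_f) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_ortho <- function(x, p) {
  m <- length(x)
  k <- seq_len(p)
  vapply(k, function(kk) {
    sqrt(2 / m) * sum(x * cos(pi * kk * (seq_len(m) - 0.5) / m))
  }, numeric(1L))
}

#' Mel-frequency cepstral coefficients
#'
#' Applies a triangular mel filterbank (HTK mel scale) to the
#' magnitude-squared spectrum, takes the natural log of the filterbank
#' energies (floored at 1e-10), and returns coefficients \code{1..p} of the
#' orthonormal DCT-II (coefficient 0, the overall log energy, is excluded).
#'
#' @param spectrum Magnitude spectrum of one frame (N/2 + 1 bins).
#' @param sample_rate Hz.
#' @param n_mels Number of mel filters (default 26).
#' @param p Number of coefficients (default 12).
#' @param fb Optional precomputed filterbank from [mel_filterbank()].
#' @return Numeric vector \code{MFCC_1..MFCC_p}.
#' @export
mfcc <- function(spectrum, sample_rate, n_mels = 26L, p = 12L, fb = NULL) {
  stopifnot(n_mels >= p)
  if (is.null(fb)) fb <- mel_filterbank(length(spectrum), sample_rate, n_mels)
  e <- log(pmax(as.numeric(fb %*% spectrum^2), 1e-10))
  dct_ortho(e, p)
}

#' Regression deltas of an MFCC track
#'
#' \eqn{\Delta c_t = \sum_{m=1}^{M} m (c_{t+m} - c_{t-m}) / (2 \sum m^2)}
#' with edge frames replicated.
#'
#' @param track Matrix of per-frame coefficients (n_frames x p).
#' @param m_window Regression half-window M in frames (default 2).
#' @return Matrix of the same shape.
#' @export
delta_mfcc <- function(track, m_window = 2L) {
  track <- as.matrix(track)
  n <- nrow(track)
  if (n == 0L) return(track)
  denom <- 2 * sum(seq_len(m_window)^2)
  pad <- rbind(track[rep(1L, m_window), , drop = FALSE], track,
               track[rep(n, m_window), , drop = FALSE])
  out <- matrix(0, nrow = n, ncol = ncol(track))
  for (m in seq_len(m_window)) {
    out <- out + m * (pad[(m_window + m) + seq_len(n), , drop = FALSE] -
                        pad[(m_window - m) + seq_len(n), , drop = FALSE])
  }
  out / denom
}
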