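#' Peak-normalize an audio clip
#'
#' Scales the waveform so that its maximum absolute amplitude is exactly 1.
#' Normalization is idempotent and invariant to positive rescaling of the
#' input.
#'
#' @param clip An [audio_clip()].
#' @return The normalized [audio_clip()].
#' @export
normalize_clip <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  peak <- max(abs(clip$samples))
  if (peak == 0) stop("normalize_clip: degenerate all-zero signal")
  clip$samples <- clip$samples / peak
  clip
}

#' Pre-emphasize a signal
#'
#' First-order high-pass pre-emphasis \eqn{y[n] = x[n] - \alpha x[n-1]}
#' with \eqn{y[0] = x[0]}. Flattens the spectral tilt of voiced audio before
#' spectral analysis.
#'
#' @param x Numeric sample sequence.
#' @param alpha Pre-emphasis coefficient in [0, 1); default 0.97.
#' @return Filtered sequence, same length as \code{x}.
#' @export
preemphasize <- function(x, alpha = 0.97) {
  stopifnot(alpha >= 0, alpha < 1)
  if (length(x) <= 1L || alpha == 0) return(x)
  c(x[1L], x[-1L] - alpha * x[-length(x)])
}

#' Slice a signal into overlapping frames
#'
#' Frame \code{j} (1-based) starts at sample \code{(j-1)*hop + 1} and holds
#' exactly \code{frame_length} samples; trailing samples that do not fill a
#' complete frame are dropped.
#'
#' @param x Numeric sample sequence.
#' @param frame_length Frame size N in samples.
#' @param hop Hop size in samples, \code{0 < hop <= frame_length}.
#' @param sample_rate Sample rate carried along for downstream analysis.
#' @return A \code{frame_sequence}: list with \code{frames} (n_frames x N
#'   matrix), \code{frame_length}, \code{hop}, \code{sample_rate}.
#' @export
frame_signal <- function(x, frame_length, hop = frame_length %/% 2L,
                         sample_rate = NA_integer_) {
  stopifnot(frame_length > 0L, hop > 0L, hop <= frame_length)
  n <- length(x)
  if (n < frame_length) {
    stop(sprintf("frame_signal: signal (%d samples) shorter than one frame (%d)",
                 n, frame_length))
  }
  n_frames <- (n - frame_length) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(starts, seq_len(frame_length), `+`)
  structure(
    list(frames = matrix(x[idx], nrow = n_frames),
         frame_length = as.integer(frame_length), hop = as.integer(hop),
         sample_rate = sample_rate),
    class = "frame_sequence"
  )
}

#' Hamming window
#'
#' \eqn{w[n] = 0.54 - 0.46 \cos(2\pi n/(N-1))}, \eqn{n = 0..N-1}.
#'
#' @param n Window length.
#' @return Numeric vector of window weights.
#' @export
hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Hamming-window frames and take FFT magnitudes
#'
#' Each frame is multiplied pointwise by the Hamming window and transformed
#' with a length-N discrete Fourier transform; the magnitudes of bins
#' \code{0..N/2} are retained.
#'
#' @param fs A \code{frame_sequence} from [frame_signal()].
#' @return A \code{spectrum_sequence}: list with \code{spectra} (n_frames x
#'   (N/2+1) magnitude matrix), \code{bin_hz} (Hz per bin) and
#'   \code{frame_length}.
#' @export
window_fft <- function(fs) {
  stopifnot(inherits(fs, "frame_sequence"), nrow(fs$frames) > 0L)
  n <- fs$frame_length
  w <- hamming_window(n)
  windowed <- fs$frames * rep(w, each = nrow(fs$frames))
  spec <- Mod(stats::mvfft(t(windowed)))[seq_len(n %/% 2L + 1L), , drop = FALSE]
  structure(
    list(spectra = t(spec),
         bin_hz = if (is.na(fs$sample_rate)) NA_real_ else fs$sample_rate / n,
         frame_length = n, sample_rate = fs$sample_rate),
    class = "spectrum_sequence"
  )
}

short_time_energy <- function(frames) rowSums(frames^2)

#' Detect cry units by double-threshold energy with a ZCR guard
#'
#' Locates the voiced expiratory segments (cry units) of a clip. Frame
#' energies at or above \code{energy_hi * max(energy)} seed a unit; the unit
#' is expanded over contiguous frames whose energy stays at or above
#' \code{energy_lo * max(energy)} and whose zero-crossing rate stays at or
#' below \code{zcr_max}. Units closer than \code{min_gap_ms} are merged and
#' units shorter than \code{min_unit_ms} are discarded.
#'
#' @param clip A normalized [audio_clip()].
#' @param energy_hi,energy_lo Seed and continuation thresholds, as fractions
#'   of the maximum frame energy (defaults 0.10 and 0.02).
#' @param zcr_max Maximum zero-crossing rate of a voiced frame (default 0.5).
#' @param min_unit_ms Minimum unit duration in ms (default 100).
#' @param min_gap_ms Gaps shorter than this (ms) are merged (default 50).
#' @param frame_length,hop Analysis frame geometry in samples.
#' @return A data.frame with columns \code{start}, \code{end}: 1-based,
#'   half-open sample intervals, disjoint and sorted. Zero rows for silence.
#' @export
detect_cry_units <- function(clip, energy_hi = 0.10, energy_lo = 0.02,
                             zcr_max = 0.5, min_unit_ms = 100, min_gap_ms = 50,
                             frame_length = 1024L, hop = 512L) {
  stopifnot(inherits(clip, "audio_clip"))
  empty <- data.frame(start = integer(0), end = integer(0))
  n <- length(clip$samples)
  if (n < frame_length) return(empty)
  fs <- frame_signal(clip$samples, frame_length, hop, clip$sample_rate)
  energy <- short_time_energy(fs$frames)
  if (max(energy) == 0) return(empty)
  zcr <- apply(fs$frames, 1L, zero_crossing_rate)
  hi <- energy_hi * max(energy)
  lo <- energy_lo * max(energy)
  active <- energy >= lo & zcr <= zcr_max
  seed <- energy >= hi
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  units <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || !any(seed[starts[k]:ends[k]])) next
    s <- (starts[k] - 1L) * hop + 1L
    e <- min((ends[k] - 1L) * hop + frame_length + 1L, n + 1L)
    units[[length(units) + 1L]] <- c(s, e)
  }
  if (length(units) == 0L) return(empty)
  u <- do.call(rbind, units)
  # merge near-adjacent units
  min_gap <- min_gap_ms / 1000 * clip$sample_rate
  merged <- u[1L, , drop = FALSE]
  if (nrow(u) > 1L) {
    for (k in 2L:nrow(u)) {
      last <- nrow(merged)
      if (u[k, 1L] - merged[last, 2L] < min_gap) {
        merged[last, 2L] <- u[k, 2L]
      } else {
        merged <- rbind(merged, u[k, , drop = FALSE])
      }
    }
  }
  # refine boundaries to sample precision: frame-level detection overshoots
  # by up to a frame on each side, so trim each unit to where its 5 ms RMS
  # envelope stays above a fraction of the unit's peak envelope
  w <- max(1L, round(0.005 * clip$sample_rate))
  env <- sqrt(stats::filter(clip$samples^2, rep(1 / w, w), sides = 2L))
  env[is.na(env)] <- 0
  for (k in seq_len(nrow(merged))) {
    idx <- merged[k, 1L]:(merged[k, 2L] - 1L)
    thr <- 0.12 * max(env[idx])
    above <- which(env[idx] >= thr)
    if (length(above) > 0L) {
      merged[k, ] <- c(idx[above[1L]], idx[above[length(above)]] + 1L)
    }
  }
  min_len <- min_unit_ms / 1000 * clip$sample_rate
  keep <- (merged[, 2L] - merged[, 1L]) >= min_len
  merged <- merged[keep, , drop = FALSE]
  data.frame(start = as.integer(merged[, 1L]), end = as.integer(merged[, 2L]))
}
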