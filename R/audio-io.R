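#' Audio clip container
#'
#' A lightweight container for a mono waveform: the amplitude sequence, its
#' sample rate, an optional class label (\code{"hunger"}, \code{"sleep"} or
#' \code{"discomfort"}) and an opaque source identifier.
#'
#' @param samples Numeric vector of amplitudes. Must be non-empty.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param label Optional class label.
#' @param source_id Optional identifier (e.g. file path) carried for reporting.
#'
#' @return An object of class \code{audio_clip}.
#' @export
audio_clip <- function(samples, sample_rate, label = NA_character_,
                       source_id = NA_character_) {
  if (length(samples) == 0L) {
    stop("audio_clip: 'samples' must be non-empty")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("audio_clip: 'sample_rate' must be a single positive number")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(sample_rate),
         label = label, source_id = source_id),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<audio_clip> %d samples @ %d Hz (%.3f s)", length(x$samples),
              x$sample_rate, dur))
  if (!is.na(x$label)) cat(sprintf(", label=%s", x$label))
  if (!is.na(x$source_id)) cat(sprintf(" [%s]", x$source_id))
  cat("\n")
  invisible(x)
}

read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a PCM WAV file
#'
#' Reads a RIFF/PCM WAV file (8/16/24/32-bit integer or 32-bit float).
#' Stereo input is mixed to mono by channel averaging; integer samples are
#' scaled to [-1, 1) by division by full scale (e.g. 32768 for 16-bit).
#'
#' @param path Path to a WAV file.
#' @param label,source_id Passed through to [audio_clip()]; \code{source_id}
#'   defaults to \code{path}.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, label = NA_character_, source_id = path) {
  if (!file.exists(path)) stop(sprintf("read_wav: file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("read_wav: not a RIFF/WAV file: %s", path))
  }
  readBin(con, "integer", n = 1L, size = 4L, endian = "little") # RIFF size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("read_wav: not a WAVE file: %s", path))
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (is.null(hdr)) break
    if (identical(hdr$id, "fmt ")) {
      body <- readBin(con, "raw", n = hdr$size)
      u16 <- function(off) {
        sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      }
      u32 <- function(off) {
        sum(as.numeric(body[off + 1:4]) * c(1, 256, 65536, 16777216))
      }
      fmt <- list(format = u16(0L), channels = u16(2L),
                  sample_rate = u32(4L), bits = u16(14L))
      if (fmt$format == 0xFFFE && hdr$size >= 26L) {
        # WAVE_FORMAT_EXTENSIBLE: subformat GUID starts with the real tag
        fmt$format <- u16(24L)
      }
    } else if (identical(hdr$id, "data")) {
      data_raw <- readBin(con, "raw", n = hdr$size)
    } else {
      seek(con, hdr$size + hdr$size %% 2L, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("read_wav: missing fmt/data chunk (compressed or malformed?): %s", path))
  }
  if (!fmt$format %in% c(1L, 3L)) {
    stop(sprintf("read_wav: unsupported (non-PCM) format tag %d: %s", fmt$format, path))
  }
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (n == 0L) stop(sprintf("read_wav: empty WAV (0 samples): %s", path))
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(as.integer(data_raw[seq_len(n)])) - 128) / 128,
    "16" = readBin(data_raw, "integer", n = n, size = 2L, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = if (fmt$format == 3L) {
      readBin(data_raw, "numeric", n = n, size = 4L, endian = "little")
    } else {
      readBin(data_raw, "integer", n = n, size = 4L, endian = "little") / 2147483648
    },
    stop(sprintf("read_wav: unsupported bit depth %d: %s", fmt$bits, path))
  )
  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)], nrow = fmt$channels))
  }
  audio_clip(x, fmt$sample_rate, label = label, source_id = source_id)
}

#' Write a 16-bit PCM WAV file
#'
#' @param clip An [audio_clip()] (or numeric vector with \code{sample_rate}).
#' @param path Output path.
#' @param sample_rate Required when \code{clip} is a bare numeric vector.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(clip, path, sample_rate = NULL) {
  if (inherits(clip, "audio_clip")) {
    x <- clip$samples
    sr <- clip$sample_rate
  } else {
    if (is.null(sample_rate)) stop("write_wav: sample_rate required for bare vectors")
    x <- as.numeric(clip)
    sr <- as.integer(sample_rate)
  }
  pcm <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(sr), con, size = 4L, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")           # block align
  writeBin(16L, con, size = 2L, endian = "little")          # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
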