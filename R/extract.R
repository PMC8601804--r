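#' Feature-extraction configuration
#'
#' Collects every tunable of the preprocessing chain and the twelve feature
#' extractors, with the package defaults. All sizes are in samples at the
#' clip's own sample rate unless stated otherwise.
#'
#' @param frame_length Analysis frame size N (default 1024 samples).
#' @param hop Hop between frames (default 512, 50\% overlap).
#' @param preemphasis Pre-emphasis coefficient (default 0.97).
#' @param energy_hi,energy_lo,zcr_max,min_unit_ms,min_gap_ms Cry-unit
#'   detector thresholds, see [detect_cry_units()].
#' @param pitch_window Dedicated pitch-analysis window in samples (default
#'   4096; a plain analysis frame holds too few periods at 250 Hz).
#' @param f0_min,f0_max,voicing_threshold Pitch search band (Hz) and voicing
#'   gate, see [pitch_autocorr()].
#' @param lpc_order LPC order for formant analysis (default 18).
#' @param n_formants Number of formants (default 6).
#' @param formant_bw_max Formant bandwidth cutoff in Hz (default 700).
#' @param n_lpcc,n_mfcc Cepstral orders (default 12 each).
#' @param n_mels Mel filters (default 26).
#' @param delta_window Delta-MFCC regression half-window (default 2 frames).
#' @param peak_alpha Peak/valley averaging fraction (default 0.2).
#' @param n_subbands Peak/valley subband count (default 4).
#' @param unit \code{"clip"} (one aggregated row per clip: per-dimension
#'   mean and sd over cry-unit frames) or \code{"frame"} (one row per frame).
#' @return A named list of class \code{feature_config}.
#' @export
feature_config <- function(frame_length = 1024L, hop = 512L, preemphasis = 0.97,
                           energy_hi = 0.10, energy_lo = 0.02, zcr_max = 0.5,
                           min_unit_ms = 100, min_gap_ms = 50,
                           pitch_window = 4096L, f0_min = 250, f0_max = 600,
                           voicing_threshold = 0.3, lpc_order = 18L,
                           n_formants = 6L, formant_bw_max = 700,
                           n_lpcc = 12L, n_mfcc = 12L, n_mels = 26L,
                           delta_window = 2L, peak_alpha = 0.2, n_subbands = 4L,
                           unit = c("clip", "frame")) {
  cfg <- as.list(environment())
  cfg$unit <- match.arg(unit)
  class(cfg) <- "feature_config"
  cfg
}

feature_schema <- function(cfg) {
  nm <- c("tm", "ta", "tv", "tz", "fb",
          sprintf("peak_%d", seq_len(cfg$n_subbands)),
          sprintf("valley_%d", seq_len(cfg$n_subbands)),
          "pitch",
          sprintf("f%d", seq_len(cfg$n_formants)),
          sprintf("lpcc_%02d", seq_len(cfg$n_lpcc)),
          sprintf("mfcc_%02d", seq_len(cfg$n_mfcc)),
          sprintf("dmfcc_%02d", seq_len(cfg$n_mfcc)))
  fam <- c("magnitude", "average", "variance", "zcr", "bandwidth",
           rep("peak", cfg$n_subbands), rep("valley", cfg$n_subbands),
           "pitch", rep("formant", cfg$n_formants), rep("lpcc", cfg$n_lpcc),
           rep("mfcc", cfg$n_mfcc), rep("dmfcc", cfg$n_mfcc))
  names(fam) <- nm
  fam
}

frame_feature_matrix <- function(segment, raw_segment, cfg, sample_rate) {
  fs <- frame_signal(segment, cfg$frame_length, cfg$hop, sample_rate)
  sp <- window_fft(fs)
  n_frames <- nrow(fs$frames)
  fam <- feature_schema(cfg)
  subbands <- default_subbands(ncol(sp$spectra), cfg$n_subbands)
  fb_mat <- mel_filterbank(ncol(sp$spectra), sample_rate, cfg$n_mels)
  out <- matrix(0, nrow = n_frames, ncol = length(fam),
                dimnames = list(NULL, names(fam)))
  mfcc_track <- matrix(0, nrow = n_frames, ncol = cfg$n_mfcc)
  pw <- cfg$pitch_window
  for (j in seq_len(n_frames)) {
    fr <- fs$frames[j, ]
    row <- sp$spectra[j, ]
    out[j, "tm"] <- frame_magnitude(fr)
    out[j, "ta"] <- frame_average(fr)
    out[j, "tv"] <- frame_variance(fr)
    out[j, "tz"] <- zero_crossing_rate(fr)
    out[j, "fb"] <- if (sum(row) == 0) 0 else spectral_bandwidth(row)
    pv <- peak_valley(row, subbands, cfg$peak_alpha)
    out[j, grep("^peak_", names(fam))] <- pv$peak
    out[j, grep("^valley_", names(fam))] <- pv$valley
    # pitch: a longer window centered on this frame, on the raw (un-pre-
    # emphasized) segment -- pre-emphasis attenuates the fundamental
    ctr <- (j - 1L) * cfg$hop + cfg$frame_length %/% 2L
    win <- min(pw, length(raw_segment))
    s0 <- max(1L, min(ctr - win %/% 2L, length(raw_segment) - win + 1L))
    pseg <- raw_segment[s0:(s0 + win - 1L)]
    min_len <- 2L * ceiling(sample_rate / cfg$f0_min)
    out[j, "pitch"] <- if (win >= min_len) {
      pitch_autocorr(pseg, sample_rate, cfg$f0_min, cfg$f0_max,
                     cfg$voicing_threshold)
    } else 0
    out[j, grep("^f[0-9]$", names(fam))] <-
      suppressWarnings(formants_lpc(fr, sample_rate, cfg$lpc_order,
                                    cfg$n_formants, cfg$formant_bw_max))
    out[j, grep("^lpcc_", names(fam))] <- suppressWarnings(lpcc(fr, cfg$n_lpcc))
    mfcc_track[j, ] <- mfcc(row, sample_rate, cfg$n_mels, cfg$n_mfcc, fb = fb_mat)
  }
  out[, grep("^mfcc_", names(fam))] <- mfcc_track
  out[, grep("^dmfcc_", names(fam))] <- delta_mfcc(mfcc_track, cfg$delta_window)
  out
}

#' Extract the twelve acoustic features from a clip
#'
#' Runs the full preprocessing chain (peak normalization, cry-unit
#' detection, per-unit pre-emphasis, framing, Hamming windowing, FFT) and
#' computes all twelve feature families on every cry-unit frame. In
#' \code{unit = "clip"} mode the per-frame values are aggregated into one
#' labeled row of per-dimension means and standard deviations; in
#' \code{unit = "frame"} mode one labeled row per frame is returned.
#'
#' @param clip An [audio_clip()].
#' @param config A [feature_config()].
#' @return A data.frame of named feature columns plus a \code{label} column,
#'   with attributes \code{schema} (ordered feature column names) and
#'   \code{families} (named map column -> feature family).
#' @export
extract_features <- function(clip, config = feature_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  clip <- normalize_clip(clip)
  units <- detect_cry_units(clip, config$energy_hi, config$energy_lo,
                            config$zcr_max, config$min_unit_ms,
                            config$min_gap_ms, config$frame_length, config$hop)
  if (nrow(units) == 0L) {
    stop(sprintf("extract_features: no cry units detected in clip '%s'",
                 clip$source_id))
  }
  blocks <- list()
  for (u in seq_len(nrow(units))) {
    raw <- clip$samples[units$start[u]:(units$end[u] - 1L)]
    if (length(raw) < config$frame_length) next
    seg <- preemphasize(raw, config$preemphasis)
    blocks[[length(blocks) + 1L]] <-
      frame_feature_matrix(seg, raw, config, clip$sample_rate)
  }
  if (length(blocks) == 0L) {
    stop(sprintf("extract_features: no cry units detected in clip '%s'",
                 clip$source_id))
  }
  mat <- do.call(rbind, blocks)
  fam <- feature_schema(config)
  if (config$unit == "frame") {
    df <- as.data.frame(mat)
    df$label <- clip$label
  } else {
    mu <- colMeans(mat)
    sd_ <- apply(mat, 2L, stats::sd)
    sd_[is.na(sd_)] <- 0
    vals <- c(rbind(mu, sd_))
    nm <- as.vector(rbind(paste0(names(fam), "_mean"), paste0(names(fam), "_sd")))
    df <- as.data.frame(as.list(stats::setNames(vals, nm)))
    df$label <- clip$label
    fam <- stats::setNames(rep(fam, each = 2L), nm)
  }
  attr(df, "schema") <- setdiff(names(df), "label")
  attr(df, "families") <- fam
  df
}

#' Extract features for a set of clips
#'
#' @param clips List of [audio_clip()] objects.
#' @param config A [feature_config()].
#' @return Row-bound feature data.frame (see [extract_features()]); row
#'   names identify the source clip, and a \code{clip} column records the
#'   clip index (useful in frame mode).
#' @export
extract_features_all <- function(clips, config = feature_config()) {
  rows <- lapply(seq_along(clips), function(i) {
    df <- extract_features(clips[[i]], config)
    df$clip <- i
    df
  })
  out <- do.call(rbind, rows)
  attr(out, "schema") <- attr(rows[[1L]], "schema")
  attr(out, "families") <- attr(rows[[1L]], "families")
  rownames(out) <- NULL
  out
}
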