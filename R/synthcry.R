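#' Synthetic cry generator configuration
#'
#' Class-conditional parameter distributions for the source-filter cry
#' synthesizer. Three presets control class separability:
#' \code{"separable"} gives the three classes disjoint fundamental-frequency
#' bands (all inside the 250-600 Hz neonate cry range) and distinct formant
#' sets; \code{"overlapping"} gives all classes the same F0 band and formants
#' differing by under 5 percent, degrading classification toward chance;
#' \code{"noiseless"} is the separable preset without additive noise and
#' with one continuous burst per clip (for exercising end-point detection
#' against exact ground truth).
#'
#' @param preset One of \code{"separable"}, \code{"overlapping"},
#'   \code{"noiseless"}.
#' @param sample_rate Hz (default 16000; the study-scale rate of 44100 is
#'   supported).
#' @param clip_duration_s Clip length in seconds (default 2; full-scale
#'   recordings run 10-60 s).
#' @param snr_db Signal-to-noise ratio in dB (default 20; \code{Inf} for no
#'   noise).
#' @param vibrato_depth Relative F0 modulation depth (default 0.02).
#' @param vibrato_rate Vibrato rate in Hz (default 5).
#' @return A \code{synth_config} list with per-class \code{f0_range},
#'   \code{formants}, burst/pause duration ranges (ms), and the global
#'   parameters.
#' @export
synth_config <- function(preset = c("separable", "overlapping", "noiseless"),
                         sample_rate = 16000L, clip_duration_s = 2,
                         snr_db = 20, vibrato_depth = 0.02, vibrato_rate = 5) {
  preset <- match.arg(preset)
  classes <- c("hunger", "sleep", "discomfort")
  if (preset == "overlapping") {
    per_class <- list(
      hunger     = list(f0_range = c(380, 440), formants = c(1000, 3000, 5000)),
      sleep      = list(f0_range = c(380, 440), formants = c(1030, 3090, 5150)),
      discomfort = list(f0_range = c(380, 440), formants = c(970, 2910, 4850))
    )
  } else {
    per_class <- list(
      hunger     = list(f0_range = c(420, 480), formants = c(1100, 3300, 5400)),
      sleep      = list(f0_range = c(280, 330), formants = c(900, 2700, 4600)),
      discomfort = list(f0_range = c(520, 580), formants = c(1300, 3900, 6200))
    )
  }
  burst_ms <- c(350, 650)
  pause_ms <- c(150, 300)
  if (preset == "noiseless") {
    snr_db <- Inf
    burst_ms <- c(1e7, 1e7)  # one burst spanning the whole clip
  }
  structure(
    list(preset = preset, classes = classes, per_class = per_class,
         burst_ms = burst_ms, pause_ms = pause_ms,
         lead_silence_ms = c(100, 250), sample_rate = as.integer(sample_rate),
         clip_duration_s = clip_duration_s, snr_db = snr_db,
         vibrato_depth = vibrato_depth, vibrato_rate = vibrato_rate,
         formant_bw = 150, glottal_tilt = 0.95, ramp_ms = 10),
    class = "synth_config"
  )
}

resonator_filter <- function(x, freq, bw, sample_rate) {
  r <- exp(-pi * bw / sample_rate)
  theta <- 2 * pi * freq / sample_rate
  as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive"))
}

#' Generate one synthetic cry clip
#'
#' Source-filter synthesis: a glottal-like impulse train at a
#' class-conditional fundamental frequency (with slow vibrato), passed
#' through the class's cascaded two-pole formant resonators, shaped by a
#' burst/pause amplitude envelope (pauses emulate inspiration), plus white
#' noise at the configured SNR. Deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @param class_label One of the configured classes.
#' @param seed Integer seed.
#' @return List with \code{clip} (an [audio_clip()]) and \code{truth}
#'   (label, drawn \code{f0}, and a data.frame of true voiced sample
#'   intervals).
#' @export
generate_clip <- function(config, class_label, seed = 1L) {
  if (!class_label %in% config$classes) {
    stop(sprintf("generate_clip: unknown class '%s'", class_label))
  }
  pc <- config$per_class[[class_label]]
  if (diff(pc$f0_range) < 0 || any(pc$f0_range < 200) || any(pc$f0_range > 700)) {
    stop("generate_clip: f0_range must lie within [200, 700] Hz")
  }
  set.seed(seed)
  sr <- config$sample_rate
  n <- round(config$clip_duration_s * sr)
  f0 <- stats::runif(1L, pc$f0_range[1L], pc$f0_range[2L])

  # burst/pause envelope with raised-cosine ramps
  env <- numeric(n)
  voiced <- list()
  pos <- round(stats::runif(1L, config$lead_silence_ms[1L],
                            config$lead_silence_ms[2L]) / 1000 * sr)
  ramp <- round(config$ramp_ms / 1000 * sr)
  while (pos < n - 2L * ramp) {
    blen <- round(stats::runif(1L, config$burst_ms[1L], config$burst_ms[2L]) /
                    1000 * sr)
    blen <- min(blen, n - pos - ramp)
    if (blen < 2L * ramp) break
    idx <- pos + seq_len(blen)
    shape <- rep(1, blen)
    up <- seq_len(ramp)
    shape[up] <- 0.5 * (1 - cos(pi * up / ramp))
    shape[blen - ramp + up] <- rev(shape[up])
    env[idx] <- shape
    voiced[[length(voiced) + 1L]] <- c(pos + 1L, pos + blen + 1L)
    pos <- pos + blen +
      round(stats::runif(1L, config$pause_ms[1L], config$pause_ms[2L]) / 1000 * sr)
  }
  if (length(voiced) == 0L) stop("generate_clip: clip too short for one burst")

  # impulse-train source with vibrato, by phase accumulation
  t <- (seq_len(n) - 1L) / sr
  f_inst <- f0 * (1 + config$vibrato_depth * sin(2 * pi * config$vibrato_rate * t))
  phase <- cumsum(f_inst / sr)
  src <- c(1, diff(floor(phase)))
  # glottal spectral tilt (~ -12 dB/oct): impulse trains are spectrally
  # flat, real glottal pulses are not
  tilt <- config$glottal_tilt
  sig <- as.numeric(stats::filter(src, tilt, method = "recursive"))
  sig <- as.numeric(stats::filter(sig, tilt, method = "recursive"))
  for (k in seq_along(pc$formants)) {
    sig <- resonator_filter(sig, pc$formants[k], config$formant_bw, sr)
  }
  sig <- sig / max(abs(sig)) * env
  if (is.finite(config$snr_db)) {
    vmask <- env > 0
    p_sig <- mean(sig[vmask]^2)
    sigma <- sqrt(p_sig / 10^(config$snr_db / 10))
    sig <- sig + stats::rnorm(n, sd = sigma)
  }
  sig <- sig / max(abs(sig)) * 0.9
  truth_voiced <- do.call(rbind, voiced)
  list(
    clip = audio_clip(sig, sr, label = class_label,
                      source_id = sprintf("synth-%s-%d", class_label, seed)),
    truth = list(label = class_label, f0 = f0,
                 voiced = data.frame(start = truth_voiced[, 1L],
                                     end = truth_voiced[, 2L]))
  )
}

#' Generate a labeled synthetic cry dataset
#'
#' Draws per-clip seeds from the master seed, generates clips for every
#' class (balanced \code{n_per_class} or explicit \code{counts}), assigns
#' alternating sex tags within class, and optionally writes 16-bit WAV
#' files plus a manifest CSV (columns file, label, sex, seed,
#' f0_true_mean).
#'
#' @param config A [synth_config()].
#' @param n_per_class Clips per class (ignored when \code{counts} given).
#' @param seed Master seed.
#' @param dir Output directory for WAVs + \code{manifest.csv}; \code{NULL}
#'   (default) keeps everything in memory.
#' @param counts Optional named integer vector of per-class counts.
#' @return List with \code{clips} (list of [generate_clip()] results) and
#'   \code{manifest} (data.frame).
#' @export
generate_dataset <- function(config, n_per_class = 10L, seed = 1L, dir = NULL,
                             counts = NULL) {
  if (is.null(counts)) {
    counts <- stats::setNames(rep(as.integer(n_per_class), length(config$classes)),
                              config$classes)
  }
  stopifnot(all(counts >= 1L))
  set.seed(seed)
  total <- sum(counts)
  clip_seeds <- sample.int(.Machine$integer.max - 1L, total)
  clips <- vector("list", total)
  rows <- vector("list", total)
  i <- 0L
  for (cl in names(counts)) {
    for (j in seq_len(counts[[cl]])) {
      i <- i + 1L
      g <- generate_clip(config, cl, clip_seeds[i])
      sex <- if (j %% 2L == 1L) "male" else "female"
      file <- NA_character_
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        file <- file.path(dir, sprintf("%s_%03d.wav", cl, j))
        write_wav(g$clip, file)
      }
      clips[[i]] <- g
      rows[[i]] <- data.frame(file = file, label = cl, sex = sex,
                              seed = clip_seeds[i], f0_true_mean = g$truth$f0)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(clips = clips, manifest = manifest)
}
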