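# Class-conditional synthetic goat lung-sound generator. The generator
# encodes the auscultation phenomenology the classifier must separate:
# breath-cycle amplitude modulation (normal 12-30 breaths/min, tachypnea
# faster), a continuous low-pitched high-energy tonal component (rhonchi)
# and recordings dominated by ambient/friction noise (noise class), with
# energy concentrated at low-mid frequencies.

CLASS_NAMES <- c("normal", "rhonchi", "tachypnea", "noise")

# Splittable deterministic sub-seed (kept below 2^31 - 1).
derive_seed <- function(seed, i) {
  ((seed %% 2147483647) * 48271 + i * 69621) %% 2147483647
}

#' Class-conditional synthesis parameters
#'
#' Draws the per-recording generative settings for one synthetic lung-sound
#' recording. Normal breathing rates are drawn in the goat resting range
#' 12-30 breaths/min; tachypnea in 40-80 breaths/min, disjoint from and
#' strictly above the normal range so the label is valid by construction.
#'
#' @param class_code Integer 0 (normal), 1 (rhonchi), 2 (tachypnea), 3 (noise).
#' @param duration_s Recording length in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Seed; all per-recording draws flow from it.
#' @param snr_db Breath-signal-to-ambient-noise ratio in dB.
#' @param noise_burst_rate Friction transients per second for the noise class.
#' @return A `synthesis_params` list, including the drawn
#'   `breaths_per_min`, `rhonchi_tone_hz` and `rhonchi_gain`.
#' @export
synthesis_params <- function(class_code, duration_s = 10, rate = 8000, seed,
                             snr_db = 15, noise_burst_rate = 1.5) {
  stopifnot(class_code %in% 0:3, duration_s > 0, rate > 0)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  bpm <- if (class_code == 2) stats::runif(1, 40, 80) else stats::runif(1, 12, 30)
  p <- list(class_code = as.integer(class_code),
            class_name = CLASS_NAMES[class_code + 1],
            duration_s = duration_s, rate = rate, seed = seed,
            breaths_per_min = bpm,
            rhonchi_tone_hz = stats::runif(1, 80, 300),
            rhonchi_gain = stats::runif(1, 2, 4),
            snr_db = snr_db, noise_burst_rate = noise_burst_rate)
  class(p) <- "synthesis_params"
  p
}

#' Breath-cycle amplitude envelope
#'
#' Periodic at `breaths_per_min`, with a dominant smooth inspiratory bump
#' over the first 35% of each cycle, a weaker expiratory bump and a small
#' baseline, so most per-cycle energy falls in the inspiratory phase.
#'
#' @param params A [synthesis_params()].
#' @param t Time grid in seconds.
#' @return Non-negative gain sequence over `t`.
#' @export
breath_envelope <- function(params, t) {
  period <- 60 / params$breaths_per_min
  ph <- (t / period) %% 1
  env <- rep(0.04, length(t))
  ins <- ph < 0.35
  env[ins] <- env[ins] + sin(pi * ph[ins] / 0.35)^2
  ex <- ph >= 0.40 & ph < 0.70
  env[ex] <- env[ex] + 0.3 * sin(pi * (ph[ex] - 0.40) / 0.30)^2
  env
}

pink_noise <- function(n) {
  # 1/f amplitude shaping of white noise in the frequency domain
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  k <- c(1, seq_len(n - 1))
  shape <- 1 / sqrt(pmin(k, n - k + 1))
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize one lung-sound recording
#'
#' Normal recordings are breath-envelope-modulated band-limited noise with
#' energy concentrated in 50-800 Hz over a faint pink ambient floor.
#' Rhonchi add a continuous low-pitched amplitude-modulated tone whose RMS
#' exceeds the breath-noise RMS by `rhonchi_gain`. Tachypnea uses the normal
#' structure at the elevated breathing rate. The noise class is pink
#' ambient noise plus Poisson-timed broadband friction transients with the
#' breath component attenuated by 14 dB. Peak amplitude never exceeds 1.
#'
#' @param params A [synthesis_params()].
#' @return An [audio_recording()] labelled with the class code.
#' @export
synth_recording <- function(params) {
  set.seed(derive_seed(params$seed, 7L))
  n <- round(params$duration_s * params$rate)
  t <- (seq_len(n) - 1) / params$rate
  env <- breath_envelope(params, t)
  bf <- signal::butter(4, c(50, 800) / (params$rate / 2), type = "pass")
  breath <- signal::filtfilt(bf$b, bf$a, stats::rnorm(n)) * env
  breath <- breath / rms(breath) * 0.1
  ambient <- pink_noise(n) * 0.1 * 10^(-params$snr_db / 20)
  y <- switch(params$class_name,
    normal = breath + ambient,
    tachypnea = breath + ambient,
    rhonchi = {
      tone <- sin(2 * pi * params$rhonchi_tone_hz * t + stats::runif(1, 0, 2 * pi))
      tone <- tone * (0.6 + 0.4 * env / max(env))
      tone <- tone / rms(tone) * 0.1 * params$rhonchi_gain
      breath + tone + ambient
    },
    noise = {
      amb <- pink_noise(n) * 0.1
      nb <- stats::rpois(1, params$noise_burst_rate * params$duration_s)
      bursts <- numeric(n)
      if (nb > 0) {
        starts <- sort(sample.int(n, nb))
        for (s0 in starts) {
          blen <- min(n - s0 + 1, round(stats::runif(1, 0.03, 0.08) * params$rate))
          decay <- exp(-seq(0, 5, length.out = blen))
          bursts[s0:(s0 + blen - 1)] <- bursts[s0:(s0 + blen - 1)] +
            stats::rnorm(blen) * decay * 0.3
        }
      }
      amb + bursts + breath * 10^(-14 / 20)
    })
  peak <- max(abs(y))
  if (peak > 0.99) y <- y * 0.99 / peak
  audio_recording(y, params$rate,
                  record_id = sprintf("synt_%s_%d", params$class_name, params$seed),
                  label = params$class_code)
}

rms <- function(x) sqrt(mean(x^2))

#' Fraction of spectral energy inside a frequency band
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param lo,hi Band edges in Hz.
#' @return Fraction of total energy in `[lo, hi]` (one-sided spectrum).
#' @export
band_energy_fraction <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(n %/% 2 + 1)]
  freqs <- (seq_along(half) - 1) * rate / n
  sum(half[freqs >= lo & freqs <= hi]) / sum(half)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes WAV files with paired `.txt` label sidecars (the interchange
#' format of the audio IO module) plus a `manifest.csv`. All randomness
#' flows from `seed` through a splittable per-file derivation, so the same
#' seed reproduces the same dataset bit for bit.
#'
#' @param n_per_class Integer vector of length 4: counts for classes 0:3.
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed.
#' @param duration_s Recording length in seconds.
#' @param rate Sampling rate in Hz.
#' @return The manifest data frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n_per_class, out_dir, seed, duration_s = 10,
                             rate = 8000) {
  stopifnot(length(n_per_class) == 4, all(n_per_class >= 0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  idx <- 0L
  for (cl in 0:3) {
    for (i in seq_len(n_per_class[cl + 1])) {
      idx <- idx + 1L
      fseed <- derive_seed(seed, idx)
      p <- synthesis_params(cl, duration_s = duration_s, rate = rate, seed = fseed)
      rec <- synth_recording(p)
      stem <- sprintf("%s_%04d", p$class_name, i)
      write_wav(rec, file.path(out_dir, paste0(stem, ".wav")))
      write_label_file(cl, file.path(out_dir, paste0(stem, ".txt")))
      rows[[idx]] <- data.frame(file = paste0(stem, ".wav"), label = cl,
                                class = p$class_name, seed = fseed,
                                breaths_per_min = p$breaths_per_min,
                                rhonchi_tone_hz = p$rhonchi_tone_hz,
                                duration_s = duration_s)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Generate an in-memory feature dataset for model training
#'
#' Convenience path used by tests and examples: synthesizes recordings,
#' bandpasses them, computes gammatonegrams and stacks model inputs.
#'
#' @param n_per_class Counts for classes 0:3.
#' @param seed Base seed.
#' @param duration_s Recording length (s).
#' @param side Model input side.
#' @param n_filters Gammatone filters.
#' @param rate Sampling rate (Hz).
#' @return List with `x` (N, side, side, 3) and integer `y` (codes 0:3).
#' @export
synth_feature_dataset <- function(n_per_class, seed, duration_s = 10,
                                  side = 96, n_filters = 64, rate = 8000) {
  bank <- make_filterbank(n_filters = n_filters, rate = rate)
  bp <- design_bandpass(rate = rate)
  n_total <- sum(n_per_class)
  x <- array(0, c(n_total, side, side, 3))
  y <- integer(n_total)
  idx <- 0L
  for (cl in 0:3) {
    for (i in seq_len(n_per_class[cl + 1])) {
      idx <- idx + 1L
      p <- synthesis_params(cl, duration_s = duration_s, rate = rate,
                            seed = derive_seed(seed, idx))
      rec <- synth_recording(p)
      filtered <- apply_bandpass(rec$samples, bp, rate = rate)
      gtg <- compute_gammatonegram(filtered, bank, rate = rate)
      x[idx, , , ] <- to_model_input(gtg, side = side)
      y[idx] <- cl
    }
  }
  list(x = x, y = y)
}
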