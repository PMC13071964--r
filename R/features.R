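# Gammatone (ERB-scale) time-frequency features: filterbank construction,
# gammatonegram computation and conversion to the fixed-size model input.

#' Equivalent rectangular bandwidth of the auditory filter at a frequency
#'
#' Glasberg-Moore fit: `ERB(f) = 24.7 * (4.37 * f / 1000 + 1)` Hz.
#'
#' @param fc Centre frequency in Hz (non-negative).
#' @return Bandwidth in Hz, strictly increasing in `fc`.
#' @export
erb_bandwidth <- function(fc) {
  if (any(fc < 0)) stop("centre frequency must be non-negative")
  24.7 * (4.37 * fc / 1000 + 1)
}

#' ERB-rate scale transforms
#'
#' `hz_to_erbrate` maps frequency to the ERB-number scale
#' (`21.4 * log10(1 + 4.37 f / 1000)`); `erbrate_to_hz` is its inverse.
#' Filterbank centres are spaced uniformly on this scale.
#'
#' @param f Frequency in Hz.
#' @param e ERB-rate value.
#' @return Transformed values.
#' @export
hz_to_erbrate <- function(f) 21.4 * log10(1 + 4.37 * f / 1000)

#' @rdname hz_to_erbrate
#' @export
erbrate_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Gammatone impulse response
#'
#' `g(t) = a t^(n-1) exp(-2 pi b ERB(fc) t) cos(2 pi fc t + phi)` for t >= 0:
#' a gamma-shaped envelope on a tonal carrier, the standard model of
#' cochlear filter shapes.
#'
#' @param t Time in seconds (non-negative).
#' @param fc Centre frequency in Hz.
#' @param n Filter order (default 4).
#' @param b Decay factor (default 1.019).
#' @param a Gain.
#' @param phi Carrier phase in radians.
#' @return Amplitudes at `t`.
#' @export
gammatone_impulse_response <- function(t, fc, n = 4, b = 1.019, a = 1, phi = 0) {
  stopifnot(all(t >= 0), n >= 1, b > 0, fc >= 0)
  a * t^(n - 1) * exp(-2 * pi * b * erb_bandwidth(fc) * t) * cos(2 * pi * fc * t + phi)
}

#' Build a gammatone filterbank
#'
#' Centre frequencies are spaced uniformly on the ERB-rate scale between
#' `f_low` and `f_high` inclusive. Each filter is realized as an FIR
#' truncation of the impulse response at `ir_s` seconds (by 128 ms the
#' gamma envelope has decayed by far more than 80 dB for these bands),
#' normalized to unit peak frequency-domain gain so filters are comparable
#' across the bank.
#'
#' @param n_filters Number of filters (>= 2).
#' @param f_low,f_high Band edges in Hz; `f_high` below Nyquist.
#' @param rate Sampling rate in Hz.
#' @param n,b Gammatone order and decay factor.
#' @param ir_s Impulse-response truncation length in seconds.
#' @return A `gammatone_filterbank`: centre frequencies, per-filter specs and
#'   the FIR taps matrix (taps x filters).
#' @export
make_filterbank <- function(n_filters = 64, f_low = 50, f_high = 2000,
                            rate = 8000, n = 4, b = 1.019, ir_s = 0.128) {
  stopifnot(n_filters >= 2, f_low > 0, f_low < f_high, f_high < rate / 2)
  cfs <- erbrate_to_hz(seq(hz_to_erbrate(f_low), hz_to_erbrate(f_high),
                           length.out = n_filters))
  cfs[1] <- f_low; cfs[n_filters] <- f_high   # pin endpoints exactly
  len <- round(ir_s * rate)
  t <- (seq_len(len) - 1) / rate
  nfft <- 2^ceiling(log2(4 * len))
  irs <- matrix(0, len, n_filters)
  gains <- numeric(n_filters)
  for (k in seq_len(n_filters)) {
    g <- gammatone_impulse_response(t, cfs[k], n = n, b = b)
    peak <- max(Mod(stats::fft(c(g, numeric(nfft - len)))))
    gains[k] <- 1 / peak
    irs[, k] <- g / peak
  }
  specs <- lapply(seq_len(n_filters), function(k) {
    list(a = gains[k], n = n, b = b, fc = cfs[k],
         erb_fc = erb_bandwidth(cfs[k]), phi = 0)
  })
  structure(list(center_freqs = cfs, specs = specs, irs = irs, rate = rate,
                 ir_s = ir_s, fft_cache = new.env(parent = emptyenv())),
            class = "gammatone_filterbank")
}

# FFT of every filter at a given transform size, cached on the bank.
bank_ffts <- function(bank, nfft) {
  key <- as.character(nfft)
  if (is.null(bank$fft_cache[[key]])) {
    h <- matrix(0 + 0i, nfft, ncol(bank$irs))
    for (k in seq_len(ncol(bank$irs)))
      h[, k] <- stats::fft(c(bank$irs[, k], numeric(nfft - nrow(bank$irs))))
    assign(key, h, envir = bank$fft_cache)
  }
  bank$fft_cache[[key]]
}

#' Compute a gammatonegram
#'
#' The segment is passed through every filter of the bank (FFT-based
#' convolution, causal alignment); per-frame mean energies are log10
#' compressed with floor `eps` so silence stays finite. Row k corresponds to
#' the k-th centre frequency, ascending, so low frequencies sit at low row
#' indices.
#'
#' @param seg A `labeled_segment`, [audio_recording()] or numeric vector.
#' @param bank A [make_filterbank()].
#' @param frame_s Analysis window in seconds.
#' @param hop_s Hop between windows in seconds; `frame_s > hop_s > 0`.
#' @param eps Log floor on frame energies.
#' @param rate Sampling rate for bare numeric input.
#' @return A `gammatonegram`: `values` (filters x frames), `center_freqs`,
#'   timing metadata and the source label if known.
#' @export
compute_gammatonegram <- function(seg, bank, frame_s = 0.025, hop_s = 0.010,
                                  eps = 1e-10, rate = NULL) {
  stopifnot(frame_s > hop_s, hop_s > 0)
  x <- if (is.numeric(seg)) seg else seg$samples
  sr <- if (is.numeric(seg)) rate else seg$rate
  if (is.null(sr)) stop("rate unknown; pass `rate` for numeric input")
  if (sr != bank$rate) stop("segment rate ", sr, " != filterbank rate ", bank$rate)
  n <- length(x)
  frame_n <- round(frame_s * sr)
  hop_n <- round(hop_s * sr)
  if (n < frame_n) stop("segment shorter than one analysis frame")
  n_frames <- (n - frame_n) %/% hop_n + 1L
  len <- nrow(bank$irs)
  nfft <- 2^ceiling(log2(n + len - 1))
  xf <- stats::fft(c(x, numeric(nfft - n)))
  hf <- bank_ffts(bank, nfft)
  nk <- ncol(bank$irs)
  vals <- matrix(0, nk, n_frames)
  starts <- (seq_len(n_frames) - 1L) * hop_n
  for (k in seq_len(nk)) {
    y <- Re(stats::fft(xf * hf[, k], inverse = TRUE))[seq_len(n)] / nfft
    cs <- c(0, cumsum(y * y))
    vals[k, ] <- (cs[starts + frame_n + 1L] - cs[starts + 1L]) / frame_n
  }
  structure(list(values = log10(eps + vals), center_freqs = bank$center_freqs,
                 frame_s = frame_s, hop_s = hop_s, rate = sr,
                 label = if (is.numeric(seg)) NULL else seg$label),
            class = "gammatonegram")
}

#' Convert a gammatonegram to the fixed-size model input
#'
#' Bilinear resize of the filters x frames matrix to `side` x `side`
#' (frequency ascending along the first axis), per-sample standardization to
#' zero mean and unit variance (variance floored, so a constant map becomes
#' all zeros), and replication to three identical channels.
#'
#' @param gtg A [compute_gammatonegram()] result.
#' @param side Output side in pixels.
#' @return A `(side, side, 3)` array with the label stored in
#'   `attr(, "label")`.
#' @export
to_model_input <- function(gtg, side = 224) {
  v <- gtg$values
  if (ncol(v) < 2 || nrow(v) < 2)
    stop("degenerate gammatonegram: need at least 2 rows and 2 frames")
  r <- EBImage::resize(v, w = side, h = side)
  mu <- mean(r)
  sdv <- stats::sd(as.vector(r))
  r <- if (sdv < 1e-8) array(0, dim(r)) else (r - mu) / sdv
  out <- array(r, c(side, side, 3))
  attr(out, "label") <- gtg$label
  out
}
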