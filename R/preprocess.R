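# Bandpass preprocessing and SMOTE class balancing.

#' Design the lung-sound Butterworth bandpass filter
#'
#' Lung-sound energy concentrates in 50-2000 Hz; a Butterworth bandpass over
#' that band strips out-of-band noise. `order` is the analog Butterworth
#' prototype order handed to the designer (the usual convention in filter
#' design code). The digital filter keeps the half-power (-3.01 dB) property
#' at both cutoffs.
#'
#' @param order Butterworth prototype order.
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < rate/2`.
#' @param rate Sampling rate in Hz.
#' @return A `bandpass_filter` with coefficient vectors `b`, `a`.
#' @export
design_bandpass <- function(order = 4, low_hz = 50, high_hz = 2000, rate = 8000) {
  stopifnot(order >= 1)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2))
    stop("need 0 < low_hz < high_hz < rate/2 (Nyquist)")
  bt <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  structure(list(b = bt$b, a = bt$a, order = order,
                 low_hz = low_hz, high_hz = high_hz, rate = rate),
            class = "bandpass_filter")
}

#' Magnitude response of a digital filter at given frequencies
#'
#' @param filt A [design_bandpass()] filter.
#' @param freq_hz Frequencies in Hz.
#' @param db Return decibels (default) instead of linear magnitude.
#' @return Numeric vector of gains.
#' @export
filter_response <- function(filt, freq_hz, db = TRUE) {
  # evaluate numerator/denominator as polynomials in z^-1
  w <- 2 * pi * freq_hz / filt$rate
  z <- exp(-1i * w)
  num <- 0 + 0i
  for (c_k in filt$b) num <- num * z + c_k
  den <- 0 + 0i
  for (c_k in filt$a) den <- den * z + c_k
  m <- Mod(num / den)
  if (db) 20 * log10(m) else m
}

#' Zero-phase bandpass filtering of a segment
#'
#' Forward-backward filtering avoids phase distortion of breath envelopes.
#'
#' @param x A `labeled_segment`, [audio_recording()] or numeric vector.
#' @param filt A [design_bandpass()] filter; its rate must match.
#' @param rate Sampling rate when `x` is a bare vector.
#' @return Same type as `x`, filtered, same length and label.
#' @export
apply_bandpass <- function(x, filt = design_bandpass(), rate = NULL) {
  xr <- if (is.numeric(x)) rate else x$rate
  if (is.null(xr)) stop("rate unknown; pass `rate` for numeric input")
  if (xr != filt$rate)
    stop("rate mismatch: signal ", xr, " Hz vs filter ", filt$rate, " Hz")
  samp <- if (is.numeric(x)) x else x$samples
  y <- signal::filtfilt(filt$b, filt$a, samp)
  if (is.numeric(x)) return(y)
  x$samples <- as.numeric(y)
  x
}

## ---- SMOTE -----------------------------------------------------------------

exhaustive_knn <- function(mat, k) {
  # same-class k nearest neighbours by Euclidean distance, self excluded
  n <- nrow(mat)
  sq <- rowSums(mat^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(mat)
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

#' Balance a class feature table with SMOTE
#'
#' Synthetic minority over-sampling: every minority class is expanded to the
#' majority-class count by interpolated samples `x_i + u * (x_nn - x_i)`
#' with `u ~ U(0, 1)` and `x_nn` one of the `k_neighbors` nearest same-class
#' neighbours of `x_i`. Original vectors are preserved untouched; synthetic
#' rows are appended. Interpolation happens in feature space (here,
#' flattened gammatonegram vectors), never on raw waveforms, so the
#' time-frequency microstructure of each parent is respected.
#'
#' @param table Named list of numeric matrices, one per class code
#'   (rows = samples, identical column counts).
#' @param k_neighbors Neighbourhood size; every minority class must have
#'   more than `k_neighbors` members.
#' @param seed Mandatory seed for reproducibility.
#' @return A list like `table` with all classes at the majority count.
#' @export
smote_balance <- function(table, k_neighbors = 5, seed) {
  if (missing(seed)) stop("a seed is required for reproducible balancing")
  stopifnot(is.list(table), length(table) >= 1)
  dims <- vapply(table, ncol, integer(1))
  if (length(unique(dims)) != 1) stop("all classes must share one vector length")
  counts <- vapply(table, nrow, integer(1))
  target <- max(counts)
  set.seed(seed)
  out <- table
  for (cl in names(table)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    x <- table[[cl]]
    n <- nrow(x)
    if (n <= k_neighbors)
      stop("class ", cl, " has ", n, " members; needs > k_neighbors = ",
           k_neighbors, " (lower k_neighbors)")
    nn <- exhaustive_knn(x, k_neighbors)
    parents <- sample.int(n, need, replace = TRUE)
    which_nn <- sample.int(k_neighbors, need, replace = TRUE)
    u <- stats::runif(need)
    neigh <- nn[cbind(parents, which_nn)]
    synth <- x[parents, , drop = FALSE] +
      u * (x[neigh, , drop = FALSE] - x[parents, , drop = FALSE])
    out[[cl]] <- rbind(x, synth)
  }
  out
}
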