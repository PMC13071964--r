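# Reading and writing mono PCM WAV recordings with ICBHI-style paired label
# sidecars, and fixed-length overlapping segmentation.

#' Construct an in-memory audio recording
#'
#' @param samples Numeric amplitudes in \[-1, 1\].
#' @param rate Sampling rate in Hz.
#' @param record_id Identifier (for files, the stem; by convention derived
#'   from the goat's ear tag).
#' @param label Optional class code: 0 normal, 1 rhonchi, 2 tachypnea, 3 noise.
#' @return An `audio_recording` object.
#' @export
audio_recording <- function(samples, rate, record_id = "rec", label = NULL) {
  stopifnot(rate > 0, length(samples) > 0)
  if (!is.null(label) && !label %in% 0:3)
    stop("label must be one of 0 (normal), 1 (rhonchi), 2 (tachypnea), 3 (noise)")
  structure(list(samples = as.numeric(samples), rate = rate,
                 record_id = record_id,
                 label = if (is.null(label)) NULL else as.integer(label)),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording '%s': %.2f s @ %d Hz%s>\n", x$record_id,
              length(x$samples) / x$rate, x$rate,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Samples are scaled to \[-1, 1\] (division by 32768) so downstream
#' thresholds are amplitude-scale-free. Multi-channel or non-PCM files are a
#' hard error rather than being silently mixed down. If a label sidecar
#' `<stem>.txt` exists next to the file it is read as the recording label.
#'
#' @param path Path to a RIFF/WAVE file.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, raw(), sz)
      u16 <- function(off) sum(as.integer(fmt_raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(fmt_raw[off + 1:4]) * 256^(0:3))
      fmt <- list(audio_format = u16(0), channels = u16(2),
                  rate = u32(4), bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), sz)
    } else {
      readBin(con, raw(), sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1) stop("only PCM WAV is supported: ", path)
  if (fmt$channels != 1)
    stop("multi-channel WAV not supported (", fmt$channels,
         " channels); refuse to mix down: ", path)
  if (fmt$bits != 16) stop("only 16-bit PCM is supported: ", path)
  ints <- readBin(data_raw, integer(), n = length(data_raw) %/% 2,
                  size = 2, signed = TRUE, endian = "little")
  stem <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  label_path <- file.path(dirname(path), paste0(stem, ".txt"))
  label <- if (file.exists(label_path)) read_label_file(label_path) else NULL
  audio_recording(ints / 32768, fmt$rate, record_id = stem, label = label)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Quantization is `round(x * 32768)` clamped to the 16-bit range, the exact
#' inverse of [read_wav()]'s scaling, so a read-write-read round trip is
#' sample-identical.
#'
#' @param rec An [audio_recording()] (or numeric vector with `rate` given).
#' @param path Output path.
#' @param rate Sampling rate when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, rate = NULL) {
  if (is.numeric(rec)) rec <- audio_recording(rec, rate)
  x <- pmin(pmax(round(rec$samples * 32768), -32768), 32767)
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wr_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_u32(36 + 2 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_u32(16)
  wr_u16(1); wr_u16(1); wr_u32(rec$rate); wr_u32(rec$rate * 2)
  wr_u16(2); wr_u16(16)
  writeChar("data", con, eos = NULL); wr_u32(2 * n)
  writeBin(as.integer(x), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a class label sidecar file
#'
#' The sidecar holds a single integer class code on its first line; anything
#' else is a hard error (fail-fast beats silent mislabeling).
#'
#' @param path Path to a `.txt` label file.
#' @return Integer in `0:3`.
#' @export
read_label_file <- function(path) {
  if (!file.exists(path)) stop("no such label file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty label file: ", path)
  tok <- trimws(lines[[1]])
  if (!grepl("^-?[0-9]+$", tok)) stop("label file must hold one integer: ", path)
  lab <- as.integer(tok)
  if (!lab %in% 0:3)
    stop("label ", lab, " outside {0,1,2,3}: ", path)
  lab
}

#' @rdname read_label_file
#' @param label Integer class code in `0:3`.
#' @export
write_label_file <- function(label, path) {
  stopifnot(label %in% 0:3)
  writeLines(as.character(as.integer(label)), path)
  invisible(path)
}

#' Cut a recording into fixed-length overlapping segments
#'
#' Windows start at `k * duration_s * (1 - overlap)` for k = 0, 1, 2, ...;
#' only windows completely inside the recording are emitted (incomplete
#' tails are discarded, not padded, to keep every segment's spectro-temporal
#' statistics comparable). Each segment inherits the recording's label.
#'
#' @param rec An [audio_recording()].
#' @param duration_s Segment duration in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return List of `labeled_segment` objects (possibly empty).
#' @export
segment_recording <- function(rec, duration_s = 10, overlap = 0.5) {
  stopifnot(duration_s > 0, overlap >= 0, overlap < 1)
  n <- length(rec$samples)
  len <- round(duration_s * rec$rate)
  stride_s <- duration_s * (1 - overlap)
  total_s <- n / rec$rate
  segs <- list()
  k <- 0
  repeat {
    start_t <- k * stride_s
    if (start_t + duration_s > total_s + 1e-9) break
    i0 <- round(start_t * rec$rate)
    segs[[k + 1]] <- structure(list(
      samples = rec$samples[(i0 + 1):(i0 + len)], rate = rec$rate,
      start_time = start_t, label = rec$label, source_id = rec$record_id),
      class = "labeled_segment")
    k <- k + 1
  }
  segs
}

#' @export
print.labeled_segment <- function(x, ...) {
  cat(sprintf("<labeled_segment %s @ %.1f s: %.1f s%s>\n", x$source_id,
              x$start_time, length(x$samples) / x$rate,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}
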