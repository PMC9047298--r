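#' Construct a squeal clip
#'
#' A `squeal_clip` is the unit of analysis: a mono, peak-normalized waveform
#' together with its sample rate and an opaque identifier. All feature
#' extractors in the package take clips as input. Amplitudes are unitless
#' because absolute sound pressure is typically unknown in free-field farm
#' recordings; every clip is therefore rescaled so that `max(abs(samples))`
#' is exactly 1.
#'
#' @param samples Numeric vector of amplitudes. Must contain at least one
#'   non-zero value (an all-zero signal cannot be peak-normalized).
#' @param sample_rate Sampling rate in Hz (positive number, e.g. 44100).
#' @param id Optional label used in feature tables.
#' @param normalize If `TRUE` (default) divide by the peak absolute
#'   amplitude so the clip peaks at 1.
#'
#' @return An object of class `squeal_clip` with fields `samples`,
#'   `sample_rate` and `id`.
#' @export
#' @examples
#' clip <- squeal_clip(sin(2 * pi * 440 * seq(0, 0.5, by = 1 / 8000)), 8000)
#' clip_duration(clip)
squeal_clip <- function(samples, sample_rate, id = "clip", normalize = TRUE) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one sample", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  }
  if (anyNA(samples)) stop("`samples` must not contain NA", call. = FALSE)
  if (normalize) samples <- normalize_samples(samples)
  structure(
    list(samples = samples, sample_rate = sample_rate, id = as.character(id)),
    class = "squeal_clip"
  )
}

# Peak normalization; idempotent. All-zero input is a degenerate signal.
normalize_samples <- function(samples) {
  peak <- max(abs(samples))
  if (peak == 0) {
    stop("degenerate signal: all samples are zero, cannot peak-normalize",
      call. = FALSE
    )
  }
  samples / peak
}

#' @export
print.squeal_clip <- function(x, ...) {
  cat(sprintf(
    "<squeal_clip '%s': %d samples @ %g Hz (%.3f s), peak %.3g>\n",
    x$id, length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate, max(abs(x$samples))
  ))
  invisible(x)
}

#' Duration of a clip in seconds
#'
#' @param clip A [squeal_clip()].
#' @return Duration in seconds (`N / sample_rate`).
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "squeal_clip"))
  if (length(clip$samples) == 0L) stop("empty clip", call. = FALSE)
  length(clip$samples) / clip$sample_rate
}

#' Read a WAV file as a mono normalized clip
#'
#' Reads RIFF/WAV audio (PCM 8/16/24/32-bit integer or 32/64-bit IEEE
#' float). Stereo recordings are converted to mono by keeping the left
#' channel and discarding the right, which matters when the two channels of
#' a field recorder differ in gain or noise pickup. Integer samples are
#' converted to float by dividing by the type's maximum magnitude, then the
#' signal is peak-normalized to the \[-1, 1\] range.
#'
#' @param path Path to a WAV file.
#' @param channel Which channel to keep for multi-channel files; only
#'   `"left"` (the first channel) is supported.
#' @param id Clip identifier; defaults to the file name.
#' @return A [squeal_clip()].
#' @export
read_wav <- function(path, channel = c("left"), id = basename(path)) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAV file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1L, size = 4L, endian = "little") # overall size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAV file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    chunk_id <- readChar(con, 4L, useBytes = TRUE)
    if (length(chunk_id) == 0L || nchar(chunk_id) < 4L) break
    chunk_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      body <- readBin(con, "raw", chunk_size)
      fmt <- list(
        audio_format = read_u16(body, 1L),
        n_channels   = read_u16(body, 3L),
        sample_rate  = read_u32(body, 5L),
        bits         = read_u16(body, 15L)
      )
    } else if (identical(chunk_id, "data")) {
      data_raw <- readBin(con, "raw", chunk_size)
    } else {
      readBin(con, "raw", chunk_size)
    }
    if (chunk_size %% 2L == 1L) readBin(con, "raw", 1L) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV file (missing fmt or data chunk): ", path,
      call. = FALSE
    )
  }

  samples <- decode_wav_samples(data_raw, fmt)
  if (fmt$n_channels > 1L) {
    # de-interleave; keep the first (left) channel
    samples <- samples[seq(1L, length(samples), by = fmt$n_channels)]
  }
  squeal_clip(samples, fmt$sample_rate, id = id)
}

read_u16 <- function(raw, offset) {
  sum(as.integer(raw[offset + 0:1]) * c(1L, 256L))
}
read_u32 <- function(raw, offset) {
  sum(as.numeric(raw[offset + 0:3]) * 256^(0:3))
}

decode_wav_samples <- function(data_raw, fmt) {
  n_bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% n_bytes
  if (fmt$audio_format == 1L) { # integer PCM
    if (fmt$bits == 8L) {
      # 8-bit WAV is unsigned, midpoint 128
      (as.integer(data_raw[seq_len(n)]) - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(data_raw, "integer", n, size = 2L, signed = TRUE,
        endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      idx <- 3L * (seq_len(n) - 1L)
      v <- as.numeric(data_raw[idx + 1L]) +
        256 * as.numeric(data_raw[idx + 2L]) +
        65536 * as.numeric(data_raw[idx + 3L])
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    } else if (fmt$bits == 32L) {
      readBin(data_raw, "integer", n, size = 4L, endian = "little") / 2^31
    } else {
      stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    }
  } else if (fmt$audio_format == 3L) { # IEEE float
    readBin(data_raw, "double", n, size = n_bytes, endian = "little")
  } else {
    stop("unsupported WAV audio format code: ", fmt$audio_format,
      call. = FALSE
    )
  }
}

#' Write a clip to a 16-bit PCM WAV file
#'
#' @param clip A [squeal_clip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "squeal_clip"))
  x <- pmax(pmin(clip$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # PCM
  writeBin(1L, con, size = 2L, endian = "little") # mono
  sr <- as.integer(round(clip$sample_rate))
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 2L, con, size = 4L, endian = "little") # byte rate
  writeBin(2L, con, size = 2L, endian = "little") # block align
  writeBin(16L, con, size = 2L, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Extract a time segment from a clip
#'
#' Returns the samples in the half-open interval `[start_s, end_s)`
#' (sample index `floor(t * sample_rate)`), re-normalized to peak 1 so the
#' segment is a valid clip on its own.
#'
#' @param clip A [squeal_clip()].
#' @param start_s,end_s Segment bounds in seconds;
#'   `0 <= start_s < end_s <= clip_duration(clip)`.
#' @param id Identifier for the new clip.
#' @return A [squeal_clip()] with `floor(end_s * fs) - floor(start_s * fs)`
#'   samples.
#' @export
extract_segment <- function(clip, start_s, end_s,
                            id = paste0(clip$id, "[", start_s, ",", end_s, ")")) {
  stopifnot(inherits(clip, "squeal_clip"))
  dur <- clip_duration(clip)
  if (!is.numeric(start_s) || !is.numeric(end_s) ||
    start_s < 0 || end_s > dur || start_s >= end_s) {
    stop(sprintf(
      "segment bounds [%g, %g) out of range for a %g s clip",
      start_s, end_s, dur
    ), call. = FALSE)
  }
  fs <- clip$sample_rate
  i0 <- floor(start_s * fs) + 1L
  i1 <- floor(end_s * fs)
  squeal_clip(clip$samples[i0:i1], fs, id = id)
}
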