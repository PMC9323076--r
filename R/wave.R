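#' Construct a mono waveform clip
#'
#' A `wave_clip` is the package's universal signal currency: an ordered vector
#' of dimensionless amplitudes (nominal range \[-1, 1\]) plus a sample rate.
#'
#' @param samples Numeric vector of amplitudes; all values must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `wave_clip` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' clip <- wave_clip(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' clip_duration(clip)
#' @export
wave_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples)) {
    vib_abort("`samples` must be numeric", "vib_invalid_parameter")
  }
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples))) {
    vib_abort("`samples` must be finite", "vib_invalid_parameter")
  }
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "wave_clip")
}

#' @export
print.wave_clip <- function(x, ...) {
  cat(sprintf("<wave_clip: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip A `wave_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

check_wave_clip <- function(clip, name = "clip") {
  if (!inherits(clip, "wave_clip")) {
    vib_abort(sprintf("`%s` must be a wave_clip", name), "vib_invalid_parameter")
  }
  invisible(clip)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Parses the RIFF container directly. Only uncompressed PCM, single-channel,
#' 16-bit files are accepted; amplitudes are scaled to \[-1, 1\].
#'
#' @param path Path to a WAV file.
#' @return A [wave_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    vib_abort(sprintf("file not found: %s", path), "vib_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    vib_abort(sprintf("not a RIFF/WAV file: %s", path), "vib_format_error")
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    vib_abort(sprintf("not a WAVE file: %s", path), "vib_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2,
                               signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, size = 2,
                           signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1)  # chunk word alignment
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    vib_abort(sprintf("missing fmt/data chunk: %s", path), "vib_format_error")
  }
  if (fmt$audio_format != 1L) {
    vib_abort("only uncompressed PCM WAV is supported", "vib_unsupported_format")
  }
  if (fmt$channels != 1L) {
    vib_abort(sprintf("only mono WAV is supported (file has %d channels)",
                      fmt$channels), "vib_unsupported_format")
  }
  if (fmt$bits != 16L) {
    vib_abort(sprintf("only 16-bit PCM is supported (file has %d bits)",
                      fmt$bits), "vib_unsupported_format")
  }
  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2, signed = TRUE, endian = "little")
  samples <- pmin(pmax(ints / 32767, -1), 1)
  wave_clip(samples, fmt$sample_rate)
}

#' Write a clip as mono 16-bit PCM WAV
#'
#' Samples outside \[-1, 1\] are clipped to full scale with a warning.
#'
#' @param clip A [wave_clip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  check_wave_clip(clip)
  s <- clip$samples
  n_over <- sum(abs(s) > 1)
  if (n_over > 0) {
    warning(sprintf("write_wav: %d sample(s) outside [-1, 1] clipped to full scale",
                    n_over), call. = FALSE)
    s <- pmin(pmax(s, -1), 1)
  }
  ints <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(ints)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bit depth
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Split a clip into fixed-length segments
#'
#' Consecutive non-overlapping segments of exactly `segment_seconds`; the
#' trailing remainder shorter than a full segment is dropped. Recordings are
#' conventionally cut into 5-second pieces before mixing and training.
#'
#' @param clip A [wave_clip()].
#' @param segment_seconds Segment length in seconds (> 0), default 5.
#' @return A list of `wave_clip` segments (possibly empty).
#' @export
segment_clip <- function(clip, segment_seconds = 5) {
  check_wave_clip(clip)
  check_number(segment_seconds, "segment_seconds", lower = 0, strict_lower = TRUE)
  seg_len <- as.integer(round(segment_seconds * clip$sample_rate))
  if (seg_len < 1L) {
    vib_abort("segment shorter than one sample", "vib_invalid_parameter")
  }
  n_seg <- length(clip$samples) %/% seg_len
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(i) {
    wave_clip(clip$samples[((i - 1L) * seg_len + 1L):(i * seg_len)],
              clip$sample_rate)
  })
}
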