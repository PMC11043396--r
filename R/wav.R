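#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the recording format the decoder expects:
#' uncompressed PCM, single channel, 16-bit samples. Samples are rescaled to
#' `[-1, 1]`. Multi-channel or non-PCM files are rejected; a sample rate other
#' than 44100 Hz triggers a warning (resampling is the caller's
#' responsibility).
#'
#' @param path Path to a `.wav` file.
#' @param source_id Identifier stored on the returned clip; defaults to the
#'   file name.
#' @return An [audio_clip()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, source_id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # total size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      if (fmt[1L] != 1L) stop("only uncompressed PCM WAV is supported")
      if (fmt[2L] != 1L) stop("only mono WAV is supported")
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little") # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM is supported")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2L,
                     signed = TRUE, endian = "little")
      samples <- pcm / 32768
    } else {
      readBin(con, "raw", size) # skip unknown chunk
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L) # chunk padding
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(sample_rate) || is.null(samples)) {
    stop("missing fmt/data chunk in ", path)
  }
  audio_clip(samples, sample_rate, source_id = source_id)
}

#' Write a mono PCM WAV file
#'
#' Writes 16-bit mono RIFF/WAVE. Samples are clipped to `[-1, 1]` and scaled
#' to the signed 16-bit range.
#'
#' @param samples Numeric vector in `[-1, 1]`, or an [audio_clip()].
#' @param path Output path.
#' @param sample_rate Samples per second; ignored when `samples` is a clip.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  if (inherits(samples, "audio_clip")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  stopifnot(is.numeric(samples), length(samples) > 0L, sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")  # PCM
  writeBin(1L, con, size = 2L, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")  # block align
  writeBin(16L, con, size = 2L, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Audio clip container
#'
#' Holds a mono recording as amplitudes in `[-1, 1]` plus its sample rate.
#'
#' @param samples Numeric amplitude vector.
#' @param sample_rate Samples per second; must be positive. 44100 Hz is the
#'   expected recording rate; other rates work but emit a warning.
#' @param source_id Opaque recording identifier.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `source_id`.
#' @export
audio_clip <- function(samples, sample_rate = 44100, source_id = NA_character_) {
  stopifnot(is.numeric(samples))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  if (sample_rate != 44100) {
    warning("sample rate is ", sample_rate,
            " Hz; the decoder is calibrated for 44100 Hz")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         source_id = source_id),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %d samples @ %g Hz (%.3f s)\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}
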