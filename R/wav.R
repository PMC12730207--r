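# Minimal RIFF/WAVE reader and writer. Supports the dialects field recorders
# actually produce: PCM 16/24/32-bit and IEEE float32, any channel count.
# No audio I/O package ships in this toolchain, so the format is handled here.

read_wav <- function(path) {
  if (!file.exists(path)) stopf("WAV file does not exist: %s", path)
  if (file.size(path) < 44) stopf("File too short to be a WAV file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little") # RIFF chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stopf("Not a RIFF/WAVE file: %s", path)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
      # WAVE_FORMAT_EXTENSIBLE: sub-format GUID starts at byte 25 of the body
      if (fmt$audio_format == 65534L && size >= 40) {
        fmt$audio_format <- sum(as.integer(body[25:26]) * c(1, 256))
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stopf("No fmt chunk found in %s", path)
  if (is.null(data_raw) || length(data_raw) == 0) stopf("No audio samples in %s", path)

  x <- decode_wav_samples(data_raw, fmt$audio_format, fmt$bits)
  nch <- max(1L, fmt$n_channels)
  n <- (length(x) %/% nch) * nch
  if (n == 0) stopf("No audio samples in %s", path)
  samples <- if (nch > 1L) rowMeans(matrix(x[seq_len(n)], ncol = nch, byrow = TRUE)) else x
  list(samples = samples, fs = fmt$sample_rate, n_channels = nch, bits = fmt$bits)
}

decode_wav_samples <- function(raw, audio_format, bits) {
  if (audio_format == 3L) {
    if (bits == 64) return(readBin(raw, "double", length(raw) %/% 8, 8, endian = "little"))
    return(readBin(raw, "double", length(raw) %/% 4, 4, endian = "little"))
  }
  if (audio_format != 1L) stopf("Unsupported WAV audio format code %d", audio_format)
  if (bits == 16) {
    readBin(raw, "integer", length(raw) %/% 2, 2, signed = TRUE, endian = "little") / 32768
  } else if (bits == 24) {
    n <- length(raw) %/% 3
    b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (bits == 32) {
    readBin(raw, "integer", length(raw) %/% 4, 4, endian = "little") / 2147483648
  } else if (bits == 8) {
    (as.integer(raw) - 128) / 128
  } else {
    stopf("Unsupported PCM bit depth: %d", bits)
  }
}

#' Write an audio clip to a WAV file
#'
#' Writes 16-bit PCM mono WAV, the interchange format used by the synthetic
#' generator and the command-line tools. Samples are clipped to \[-1, 1\].
#'
#' @param clip an [audio_clip()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(as.integer(clip$fs), con, 4, endian = "little")
  writeBin(as.integer(clip$fs * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
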