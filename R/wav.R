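# Minimal RIFF/WAVE PCM reader and writer (16-bit), enough to round-trip the
# mono recordings this package measures. Stereo input is averaged to mono.

#' Read a PCM WAV file into a recording
#'
#' Supports 8/16/32-bit integer PCM; multi-channel audio is averaged to mono.
#' Samples are returned normalized to \[-1, 1\].
#'
#' @param path Path to a WAV file.
#' @param species,class,segment Metadata attached to the [recording()].
#' @return A [recording()] object.
#' @export
read_wav <- function(path, species = NA_character_, class = NA_character_,
                     segment = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_pf("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_pf("not a WAVE file: ", path)

  sr <- NULL; bits <- NULL; channels <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1) stop_pf("only PCM WAV is supported (format tag ", fmt, ")")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop_pf("data chunk before fmt chunk")
      bytes <- bits %/% 8
      n <- sz %/% bytes
      data <- readBin(con, "integer", n, size = bytes, signed = bits > 8,
                      endian = "little")
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(data) && !is.null(sr)) break
  }
  if (is.null(data)) stop_pf("no data chunk found in ", path)
  scale <- 2^(bits - 1)
  x <- if (bits == 8) (data - 128) / 128 else data / scale
  if (channels > 1) {
    x <- colMeans(matrix(x, nrow = channels))
  }
  recording(x, sr, species = species, class = class, segment = segment)
}

#' Write a recording (or waveform) to a 16-bit PCM WAV file
#'
#' @param rec A [recording()] or numeric waveform in \[-1, 1\].
#' @param path Output path.
#' @param sample_rate Required when `rec` is a bare waveform.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sample_rate = NULL) {
  if (inherits(rec, "recording")) {
    wave <- rec$wave
    sr <- rec$sample_rate
  } else {
    wave <- as.numeric(rec)
    sr <- sample_rate
    if (is.null(sr)) stop_pf("supply `sample_rate` for a bare waveform")
  }
  pcm <- as.integer(pmax(-32768, pmin(32767, round(wave * 32767))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
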