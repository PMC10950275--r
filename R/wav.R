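# Minimal RIFF/WAVE PCM reader and writer.
#
# Recordings are acquired as .wav files; only uncompressed PCM is
# meaningful here. Integer full scale maps to the normalized amplitude
# +/-1 that clipping detection is defined against. No audio package is
# relied on: the subset of RIFF needed (fmt + data chunks, 8/16/24-bit
# integer and 32-bit float) is parsed directly.

#' Read a PCM WAV recording
#'
#' Parses a RIFF/WAVE file with 1 or 2 channels of 8/16/24-bit integer or
#' 32-bit float PCM. Integer samples are scaled so that full scale maps to
#' +/-1; the sampling rate is taken from the header.
#'
#' @param path Path to a `.wav` file.
#' @param species,plant_id Optional metadata attached to the recording.
#' @return A [recording()] with amplitudes in `[-1, 1]`.
#' @export
read_wav <- function(path, species = NA_character_, plant_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))  # skip unknown chunk (padded)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in ", path)
  if (is.null(data_raw)) stop("no data chunk in ", path)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported audio_format ", fmt$audio_format,
         " (only uncompressed PCM is supported)")
  if (fmt$channels > 2L)
    stop("unsupported channel count ", fmt$channels, " (1 or 2 supported)")

  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                   endian = "little") / 32768,
    "24" = {
      n3 <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(n3 * 3)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3L)
        readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little")
      else
        readBin(data_raw, "integer", length(data_raw) %/% 4, 4,
                endian = "little") / 2147483648
    },
    stop("unsupported bit depth ", fmt$bits))

  nframes <- length(x) %/% fmt$channels
  samples <- matrix(x[seq_len(nframes * fmt$channels)],
                    ncol = fmt$channels, byrow = TRUE)
  recording(samples, fmt$sample_rate, species = species, plant_id = plant_id,
            source = path)
}

#' Write a recording as 16-bit PCM WAV
#'
#' Amplitudes are clamped to `[-1, 1]` and quantized to 16-bit integers, so
#' a write/read round trip preserves samples to within one quantization
#' step (2^-15).
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "plant_recording"))
  x <- pmin(pmax(as.vector(t(rec$samples)), -1), 1)
  pcm <- pmin(as.integer(round(x * 32768)), 32767L)  # symmetric with read scale
  nch <- rec$channel_count
  fs <- as.integer(round(rec$sampling_rate))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * nch * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(nch * 2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
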