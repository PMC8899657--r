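## Minimal RIFF/WAVE PCM I/O for mono signals (16/24/32-bit integer read,
## 16-bit write). Kept deliberately small: the package only needs to
## exchange mono speech tokens with external tools.

#' Read a mono PCM WAV file
#'
#' @param path File path.
#' @param ref_db_spl Calibration attached to the samples (dB SPL of unit
#'   RMS).
#' @return A [calibrated_signal()] with samples in \[-1, 1\].
#' @export
read_wav <- function(path, ref_db_spl = 100) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      if (fmt$channels != 1) stop("only mono WAV files are supported", call. = FALSE)
      bytes <- fmt$bits / 8
      n <- size / bytes
      x <- if (fmt$bits == 16) {
        readBin(con, "integer", n, 2, endian = "little") / 2^15
      } else if (fmt$bits == 24) {
        raw <- readBin(con, "raw", size)
        m <- matrix(as.integer(raw), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        ifelse(v >= 2^23, v - 2^24, v) / 2^23
      } else if (fmt$bits == 32) {
        readBin(con, "integer", n, 4, endian = "little") / 2^31
      } else {
        stop("unsupported bit depth: ", fmt$bits, call. = FALSE)
      }
      return(calibrated_signal(x, fmt$sample_rate, ref_db_spl))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}

#' Write a calibrated signal as a 16-bit mono PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] before quantization.
#'
#' @param x A [calibrated_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "calibrated_signal"))
  pcm <- as.integer(round(clamp(x$samples, -1, 1) * (2^15 - 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # PCM
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(x$sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(2 * x$sample_rate_hz), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
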