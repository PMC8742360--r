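# Minimal RIFF/WAVE reader and writer (PCM 16-bit and IEEE float32,
# any channel count). Calibrated physical channels (Pa, kPa, ml/s) are
# stored as float32 with units declared in a YAML sidecar, since WAV itself
# carries no units.

#' Read a WAV file
#'
#' Supports uncompressed PCM (16-bit) and IEEE float (32-bit) WAV files with
#' any number of channels. PCM samples are rescaled to \[-1, 1).
#'
#' @param path File path.
#' @return A list with `data` (numeric matrix, samples x channels), `fs`
#'   (sampling rate, Hz), and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV: ", path, call. = FALSE)
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(dat, "integer", length(dat) / 2, 2, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32): ", path, call. = FALSE)
  }
  data <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  list(data = data, fs = fmt$fs, bits = fmt$bits)
}

#' Write a WAV file
#'
#' @param data Numeric vector or matrix (samples x channels).
#' @param fs Sampling rate, Hz.
#' @param path Output path.
#' @param bits 32 (IEEE float, default; preserves calibrated physical
#'   values) or 16 (PCM; values clipped to \[-1, 1)).
#' @return `path`, invisibly.
#' @export
write_wav <- function(data, fs, path, bits = 32L) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(is.numeric(data), bits %in% c(16L, 32L))
  nch <- ncol(data)
  interleaved <- as.numeric(t(data))
  if (bits == 16L) {
    pcm <- as.integer(pmin(pmax(round(interleaved * 32768), -32768), 32767))
    payload <- writeBin(pcm, raw(), size = 2, endian = "little")
    fmt_code <- 1L
  } else {
    payload <- writeBin(interleaved, raw(), size = 4, endian = "little")
    fmt_code <- 3L
  }
  block_align <- nch * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(payload)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(fmt_code), con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
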