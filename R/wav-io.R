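#' Read a RIFF WAV file
#'
#' Minimal WAV reader supporting PCM-16 and IEEE float-32 encodings,
#' mono or multi-channel. Returns samples as a numeric matrix with one
#' column per channel, scaled to \[-1, 1\] for PCM data.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (n x channels numeric matrix), `rate`
#'   (sampling rate in Hz) and `bits` (bits per sample).
#' @export
read_wav <- function(path) {
  stop_if(!file.exists(path), paste("file not found:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stop_if(!identical(riff, "RIFF"), "not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  stop_if(!identical(wave, "WAVE"), "not a WAVE file")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate     = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block    = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  stop_if(is.null(fmt) || is.null(data_raw), "missing fmt or data chunk")

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 endian = "little", signed = TRUE) / 32767
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM-16 or float-32)", call. = FALSE)
  }
  stop_if(length(x) == 0, "zero-length audio")
  samples <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  list(samples = samples, rate = fmt$rate, bits = fmt$bits)
}

#' Write a RIFF WAV file
#'
#' @param samples Numeric vector (mono) or n x channels matrix in \[-1, 1\].
#' @param path Output path.
#' @param rate Sampling rate in Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate = 16000, bits = 16) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stop_if(!bits %in% c(16, 32), "bits must be 16 or 32")
  ch <- ncol(samples)
  inter <- as.vector(t(samples))  # interleave channels
  bytes_per <- bits / 8
  data_size <- length(inter) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * ch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(ch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(inter, 1), -1) * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(inter), con, 4, endian = "little")
  }
  invisible(path)
}
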