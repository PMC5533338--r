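#' Read a RIFF/WAVE audio file
#'
#' Reads mono or multi-channel WAV files in integer PCM (16- or 24-bit) or
#' IEEE float (32- or 64-bit) encoding. Integer samples are rescaled to
#' `[-1, 1)` (division by 2^15 or 2^23); float samples are returned as stored.
#' The sample rate is taken from the file header; no resampling is performed.
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `samples` (numeric vector for mono, or a
#'   matrix with one column per channel), `rate` (samples per second),
#'   `bits` (bits per sample) and `format` (`"pcm"` or `"float"`).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = .le_uint(body[1:2]),
        n_channels   = .le_uint(body[3:4]),
        sample_rate  = .le_uint(body[5:8]),
        bits         = .le_uint(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip unknown chunk
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in ", path)
  if (is.null(data_raw)) stop("no data chunk in ", path)

  x <- switch(
    as.character(fmt$audio_format),
    "1" = .decode_pcm(data_raw, fmt$bits, path),
    "3" = .decode_float(data_raw, fmt$bits, path),
    stop("unsupported WAV audio format tag ", fmt$audio_format, " in ", path)
  )
  nch <- fmt$n_channels
  if (nch > 1) {
    x <- matrix(x, ncol = nch, byrow = TRUE)
  }
  list(samples = x, rate = fmt$sample_rate, bits = fmt$bits,
       format = if (fmt$audio_format == 1) "pcm" else "float")
}

#' Write a RIFF/WAVE audio file
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#'   For `"pcm16"`, values are clipped to `[-1, 1]` and quantized to 16 bits;
#'   for the float formats they are stored as-is (`"float64"` is lossless for
#'   R doubles).
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @param format One of `"float64"`, `"float32"`, `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, format = c("float64", "float32", "pcm16")) {
  format <- match.arg(format)
  if (is.matrix(samples)) {
    nch <- ncol(samples)
    interleaved <- as.numeric(t(samples))
  } else {
    nch <- 1L
    interleaved <- as.numeric(samples)
  }
  bits <- switch(format, float64 = 64L, float32 = 32L, pcm16 = 16L)
  tag <- if (format == "pcm16") 1L else 3L
  bytes_per <- bits %/% 8L
  data_size <- length(interleaved) * bytes_per
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(tag, con, 2, endian = "little")
  writeBin(nch, con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * nch * bytes_per), con, 4, endian = "little")  # byte rate
  writeBin(as.integer(nch * bytes_per), con, 2, endian = "little")         # block align
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmin(pmax(round(interleaved * 32768), -32768), 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(interleaved, con, bytes_per, endian = "little")
  }
  invisible(path)
}

# little-endian unsigned integer from raw bytes
.le_uint <- function(b) {
  sum(as.numeric(b) * 256^(seq_along(b) - 1))
}

.decode_pcm <- function(raw, bits, path) {
  if (bits == 16) {
    v <- readBin(raw, "integer", length(raw) %/% 2L, 2, signed = TRUE,
                 endian = "little")
    v / 32768
  } else if (bits == 24) {
    n <- length(raw) %/% 3L
    b <- as.integer(raw)
    i1 <- b[seq(1L, 3L * n, by = 3L)]
    i2 <- b[seq(2L, 3L * n, by = 3L)]
    i3 <- b[seq(3L, 3L * n, by = 3L)]
    v <- i1 + i2 * 256 + i3 * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("unsupported PCM bit depth ", bits, " in ", path)
  }
}

.decode_float <- function(raw, bits, path) {
  if (bits == 32) {
    readBin(raw, "double", length(raw) %/% 4L, 4, endian = "little")
  } else if (bits == 64) {
    readBin(raw, "double", length(raw) %/% 8L, 8, endian = "little")
  } else {
    stop("unsupported float bit depth ", bits, " in ", path)
  }
}
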