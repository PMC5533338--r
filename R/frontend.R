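#' Resolve the spectrogram frame geometry
#'
#' A streaming spectrogram cannot honour an arbitrary frame interval: the hop
#' between successive FFTs must be a whole number of audio samples, so the
#' requested interval is quantized. At 44.1 kHz a requested 1.5 ms becomes
#' `round(66.15) = 66` samples, i.e. an effective interval of
#' `66/44.1 ~ 1.4966` ms. All downstream timing (recognition-window depth,
#' frame timestamps, de-bounce clocks) is expressed in this effective interval.
#'
#' Rounding is half-away-from-zero (`round_half_away(44.1 * 1.0) = 44`).
#'
#' @param fft_size FFT length in samples. Default 256.
#' @param interval_ms Requested frame interval in milliseconds. Default 1.5.
#' @param sample_rate Sample rate in Hz. Default 44100.
#' @param band Two-element numeric, low/high edge of the analysis band in Hz
#'   (bins with centre frequency inside the closed interval are kept).
#'   Default `c(1000, 8000)`.
#' @param window_ms Depth of the recognition window in milliseconds: the
#'   classifier sees the most recent `n_frames = round(window_ms /
#'   effective_interval)` frames. Default 50.
#' @return An object of class `"frame_config"`: a list with `fft_size`,
#'   `interval_ms` (requested), `sample_rate`, `band`, `window_ms`, plus the
#'   derived `hop` (samples), `effective_interval_ms`, `n_frames`, `bins`
#'   (0-based one-sided FFT bin indices inside the band) and `n_bins`.
#' @examples
#' cfg <- frame_config()                 # 256-pt FFT, 1.5 ms, 1-8 kHz, 50 ms
#' cfg$hop                               # 66
#' cfg$effective_interval_ms             # ~1.4966
#' @export
frame_config <- function(fft_size = 256, interval_ms = 1.5, sample_rate = 44100,
                         band = c(1000, 8000), window_ms = 50) {
  stopifnot(length(band) == 2, fft_size >= 1)
  if (interval_ms <= 0) stop("frame interval must be positive")
  if (band[1] > band[2]) stop("band low edge exceeds high edge")
  if (band[1] < 0 || band[2] > sample_rate / 2) {
    stop("band must lie within (0, sample_rate/2): got [",
         band[1], ", ", band[2], "] at rate ", sample_rate)
  }
  hop <- round_half_away(sample_rate * interval_ms / 1000)
  if (hop < 1) stop("frame interval too small: hop of ", hop, " samples")
  if (hop > fft_size) {
    stop("frame interval too large: hop (", hop,
         " samples) exceeds FFT size (", fft_size, ")")
  }
  effective_interval_ms <- hop / sample_rate * 1000
  n_frames <- as.integer(round_half_away(window_ms / effective_interval_ms))
  if (n_frames < 1) stop("recognition window shorter than one frame")
  cfg <- structure(
    list(fft_size = as.integer(fft_size), interval_ms = interval_ms,
         sample_rate = sample_rate, band = as.numeric(band),
         window_ms = window_ms, hop = as.integer(hop),
         effective_interval_ms = effective_interval_ms, n_frames = n_frames),
    class = "frame_config")
  cfg$bins <- band_bins(cfg)
  cfg$n_bins <- length(cfg$bins)
  cfg
}

#' @export
print.frame_config <- function(x, ...) {
  cat("Frame configuration:\n")
  cat(sprintf("  FFT size        : %d samples (Hamming window)\n", x$fft_size))
  cat(sprintf("  sample rate     : %g Hz\n", x$sample_rate))
  cat(sprintf("  frame interval  : requested %g ms -> hop %d samples -> effective %.4f ms\n",
              x$interval_ms, x$hop, x$effective_interval_ms))
  cat(sprintf("  band            : %g-%g Hz (%d bins)\n",
              x$band[1], x$band[2], x$n_bins))
  cat(sprintf("  window          : %g ms = %d frames (input dim %d)\n",
              x$window_ms, x$n_frames, x$n_frames * x$n_bins))
  invisible(x)
}

#' Round half away from zero
#'
#' `round_half_away(44.1) == 44`, `round_half_away(66.15) == 66`,
#' `round_half_away(4.5) == 5` (base R's `round()` would give 4).
#'
#' @param x Numeric.
#' @return Numeric, rounded to the nearest integer with ties away from zero.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' One-sided FFT bin indices inside the analysis band
#'
#' Bin `i` (0-based) has centre frequency `i * sample_rate / fft_size`; bins
#' whose centre lies in the closed interval `[band[1], band[2]]` are selected.
#'
#' @param config A [frame_config()].
#' @return Integer vector of 0-based bin indices.
#' @export
band_bins <- function(config) {
  df <- config$sample_rate / config$fft_size
  all_bins <- 0:(config$fft_size %/% 2)
  f <- all_bins * df
  sel <- all_bins[f >= config$band[1] & f <= config$band[2]]
  if (length(sel) == 0) {
    stop("analysis band [", config$band[1], ", ", config$band[2],
         "] Hz contains no FFT bin centres")
  }
  as.integer(sel)
}

# Symmetric Hamming window, cached per size.
.hamming_cache <- new.env(parent = emptyenv())
.hamming <- function(n) {
  key <- as.character(n)
  w <- .hamming_cache[[key]]
  if (is.null(w)) {
    w <- as.numeric(signal::hamming(n))
    .hamming_cache[[key]] <- w
  }
  w
}

#' Band-limited power spectrum of one analysis buffer
#'
#' Applies the Hamming window to exactly `fft_size` samples, computes the FFT
#' and returns the squared magnitudes of the one-sided bins inside the
#' analysis band. No 1/N or window-gain normalization is applied: the
#' per-window z-scoring performed before classification makes absolute scale
#' irrelevant, and leaving spectra un-normalized keeps the training and
#' streaming paths trivially identical.
#'
#' @param audio_window Numeric vector of exactly `config$fft_size` samples.
#' @param config A [frame_config()].
#' @return Numeric vector of length `config$n_bins` (linear power units).
#' @export
compute_frame <- function(audio_window, config) {
  if (length(audio_window) != config$fft_size) {
    stop("compute_frame needs exactly ", config$fft_size, " samples, got ",
         length(audio_window))
  }
  X <- stats::fft(audio_window * .hamming(config$fft_size))
  Mod(X[config$bins + 1L])^2
}

# All frames of a clip at once. Returns n_bins x n_frames_total matrix plus
# the end-sample index of each frame. Frame k (1-based) covers samples
# (k-1)*hop + 1 .. (k-1)*hop + fft_size, i.e. it ends at fft_size + (k-1)*hop.
# mvfft over a strided copy of the clip keeps this fast for long clips.
.frames_of_clip <- function(samples, config) {
  n <- length(samples)
  if (n < config$fft_size) {
    stop("clip shorter (", n, " samples) than one FFT buffer (",
         config$fft_size, ")")
  }
  k <- (n - config$fft_size) %/% config$hop + 1L
  starts <- (seq_len(k) - 1L) * config$hop
  idx <- outer(seq_len(config$fft_size), starts, "+")
  M <- matrix(samples[idx], nrow = config$fft_size) * .hamming(config$fft_size)
  X <- stats::mvfft(M)
  P <- Mod(X[config$bins + 1L, , drop = FALSE])^2
  list(power = P, end_sample = config$fft_size + starts)
}

#' Compute the full frame sequence of an audio stream
#'
#' Offline equivalent of the streaming front end: the first frame is emitted
#' once `fft_size` samples exist (no zero-padded warm-up) and frame `k` ends
#' at sample `fft_size + (k-1) * hop`. Feeding the same audio through the
#' streaming detector in arbitrary chunk sizes yields the identical sequence.
#'
#' @param audio Numeric vector of samples, or a list with elements `samples`
#'   and `rate` (the rate is then checked against `config$sample_rate`).
#' @param config A [frame_config()].
#' @return A list with `power` (`n_bins x n_frames_total` matrix, one column
#'   per frame), `end_sample` (newest audio sample included in each frame)
#'   and `time_ms` (end-sample time of each frame).
#' @export
stream_frames <- function(audio, config) {
  samples <- .as_samples(audio, config$sample_rate)
  fr <- .frames_of_clip(samples, config)
  fr$time_ms <- fr$end_sample / config$sample_rate * 1000
  fr
}

.as_samples <- function(audio, expected_rate = NULL) {
  if (is.list(audio)) {
    if (!is.null(expected_rate) && !is.null(audio$rate) &&
        audio$rate != expected_rate) {
      stop("sample-rate mismatch: stream is ", audio$rate,
           " Hz but configuration expects ", expected_rate, " Hz")
    }
    audio$samples
  } else {
    as.numeric(audio)
  }
}
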