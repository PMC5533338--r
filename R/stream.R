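#' Create a streaming detector state
#'
#' The live detection loop keeps two circular stores: the most recent
#' `fft_size` audio samples, and the most recent `n_frames` band-limited
#' power spectra. Every `hop` new samples a frame is computed and pushed; once
#' the spectral ring is full, the recognition vector is assembled, normalized
#' exactly as during training, and run through the network. An event is
#' emitted on an upward threshold crossing (previous frame at or below the
#' threshold, current frame above), after which that syllable is suppressed
#' for the de-bounce interval; computation continues during suppression, only
#' emission is withheld. No event can be emitted before the spectral ring
#' first fills.
#'
#' The state is an environment mutated in place by [feed()], so audio can be
#' delivered in chunks of any size; the emitted event sequence is identical
#' for any chunking of the same audio.
#'
#' @param model A fitted `"syllable_detector"`.
#' @return An environment of class `"detector_state"`.
#' @export
detector_state <- function(model) {
  stopifnot(inherits(model, "syllable_detector"))
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$buf <- numeric(0)          # trailing samples still needed
  st$buf_start <- 1L            # absolute index of buf[1]
  st$nseen <- 0L                # total samples consumed
  st$next_end <- model$config$fft_size  # absolute end sample of next frame
  st$ring <- matrix(0, model$config$n_bins, model$config$n_frames)
  st$ring_filled <- 0L
  st$frame_idx <- 0L
  st$prev_out <- rep(-Inf, model$n_targets)
  st$last_trigger_frame <- rep(-Inf, model$n_targets)
  # de-bounce clock in effective-interval units, rounded up
  st$debounce_frames <- ceiling(model$debounce_ms /
                                  model$config$effective_interval_ms)
  class(st) <- c("detector_state", "environment")
  st
}

#' Feed audio into a streaming detector
#'
#' @param state A [detector_state()] (mutated in place).
#' @param chunk Numeric sample vector, or `list(samples, rate)` (the rate is
#'   checked against the model).
#' @param chunk_samples If supplied, `chunk` is internally re-delivered in
#'   sub-chunks of this size (convenience for whole-file feeding).
#' @return Data frame of newly emitted detection events: `syllable`,
#'   `trigger_sample` (end sample of the triggering frame), `trigger_time_s`,
#'   `output_value`.
#' @export
feed <- function(state, chunk, chunk_samples = NULL) {
  stopifnot(inherits(state, "detector_state"))
  model <- state$model
  samples <- .as_samples(chunk, model$config$sample_rate)
  if (length(samples) < 1) stop("chunk must contain at least one sample")
  if (!is.null(chunk_samples)) {
    ev <- list()
    idx <- 1L
    while (idx <= length(samples)) {
      sub <- samples[idx:min(idx + chunk_samples - 1L, length(samples))]
      ev[[length(ev) + 1L]] <- feed(state, sub)
      idx <- idx + chunk_samples
    }
    return(do.call(rbind, ev))
  }

  cfg <- model$config
  state$buf <- c(state$buf, samples)
  state$nseen <- state$nseen + length(samples)
  events <- list()
  while (state$next_end <= state$nseen) {
    i0 <- state$next_end - cfg$fft_size + 1L - state$buf_start + 1L
    win <- state$buf[i0:(i0 + cfg$fft_size - 1L)]
    frame <- compute_frame(win, cfg)
    state$ring <- cbind(state$ring[, -1L, drop = FALSE], frame)
    state$ring_filled <- min(state$ring_filled + 1L, cfg$n_frames)
    state$frame_idx <- state$frame_idx + 1L
    if (state$ring_filled == cfg$n_frames) {
      xi <- matrix(as.vector(state$ring), ncol = 1)
      xi <- .window_normalize_cols(xi)
      xi <- apply_feature_norm(model$norm, xi)
      y <- as.vector(model$params$W1 %*%
                       tanh(model$params$W0 %*% xi + model$params$b0) +
                       model$params$b1)
      for (k in seq_len(model$n_targets)) {
        crossing <- state$prev_out[k] <= model$thresholds[k] &&
          y[k] > model$thresholds[k]
        free <- (state$frame_idx - state$last_trigger_frame[k]) >=
          state$debounce_frames
        if (crossing && free) {
          events[[length(events) + 1L]] <- data.frame(
            syllable = k, trigger_sample = state$next_end,
            trigger_time_s = state$next_end / cfg$sample_rate,
            output_value = y[k])
          state$last_trigger_frame[k] <- state$frame_idx
        }
      }
      state$prev_out <- y
    }
    state$next_end <- state$next_end + cfg$hop
  }
  # retain only the samples future frames still need
  keep_from <- state$next_end - cfg$fft_size + 1L
  if (keep_from > state$buf_start) {
    state$buf <- state$buf[(keep_from - state$buf_start + 1L):length(state$buf)]
    state$buf_start <- keep_from
  }
  if (length(events)) do.call(rbind, events) else .empty_events()
}

.empty_events <- function() {
  data.frame(syllable = integer(0), trigger_sample = integer(0),
             trigger_time_s = numeric(0), output_value = numeric(0))
}

#' Detect syllables in a WAV file by simulated streaming
#'
#' Reads a mono WAV file and feeds it through the streaming detector in small
#' chunks, emulating a live audio loop. Equivalent to a single [feed()] of
#' the whole file.
#'
#' @param model A fitted `"syllable_detector"`.
#' @param wav_path Path to a mono WAV file at the model's sample rate, or a
#'   numeric sample vector / `list(samples, rate)`.
#' @param chunk_samples Chunk size in samples. Default 32.
#' @return Data frame of detection events (see [feed()]).
#' @export
detect_file <- function(model, wav_path, chunk_samples = 32) {
  audio <- if (is.character(wav_path)) read_wav(wav_path) else wav_path
  samples <- .as_samples(audio, model$config$sample_rate)
  if (is.matrix(samples)) {
    stop("detect_file expects mono audio; got ", ncol(samples), " channels")
  }
  state <- detector_state(model)
  ev <- feed(state, samples, chunk_samples = chunk_samples)
  if (is.null(ev)) .empty_events() else ev
}

#' Write an event log as delimited text
#'
#' @param events Data frame from [feed()] / [detect_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the stereo ground-truth test file for a corpus
#'
#' Left channel: all clips concatenated (songs first, then non-song clips).
#' Right channel: a unit impulse at every canonical target time, silent
#' elsewhere. Played through any audio device, the left channel drives the
#' detector while the right channel provides the ground-truth trigger. The
#' clip order and sample offsets are recorded in a sidecar
#' `<path>.clips.tsv`.
#'
#' @param corpus An `"annotated_corpus"`.
#' @param path Output WAV path.
#' @param format Sample format for [write_wav()]. Default `"float32"`.
#' @return Invisibly, a list with the concatenation layout (`offset_samples`
#'   per clip) and the absolute impulse sample indices.
#' @export
write_test_file <- function(corpus, path, format = "float32") {
  stopifnot(inherits(corpus, "annotated_corpus"))
  clips <- c(corpus$songs, corpus$nonsong)
  lens <- vapply(clips, length, integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  left <- unlist(clips)
  right <- numeric(length(left))
  impulse_samples <- integer(0)
  for (i in seq_along(corpus$songs)) {
    k <- offsets[i] + round(corpus$canonical_times[i, ] / 1000 * corpus$rate)
    right[k] <- 1
    impulse_samples <- c(impulse_samples, k)
  }
  write_wav(cbind(left, right), corpus$rate, path, format = format)
  sidecar <- data.frame(
    clip = seq_along(clips),
    is_song = rep(c(1L, 0L), c(length(corpus$songs), length(corpus$nonsong))),
    offset_samples = offsets, length_samples = lens)
  utils::write.table(sidecar, paste0(path, ".clips.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(offset_samples = offsets, impulse_samples = impulse_samples))
}

#' Read back a stereo ground-truth test file
#'
#' @param path WAV path written by [write_test_file()].
#' @return List with `audio` (left-channel samples), `rate`,
#'   `canonical_times_ms` (times of the right-channel impulses on the
#'   concatenated clock) and, if the sidecar is present, the clip layout.
#' @export
read_test_file <- function(path) {
  w <- read_wav(path)
  if (!is.matrix(w$samples) || ncol(w$samples) != 2) {
    stop("expected a stereo test file: ", path)
  }
  impulses <- which(w$samples[, 2] != 0)
  sidecar_path <- paste0(path, ".clips.tsv")
  layout <- if (file.exists(sidecar_path)) {
    utils::read.delim(sidecar_path)
  } else NULL
  list(audio = w$samples[, 1], rate = w$rate,
       canonical_times_ms = impulses / w$rate * 1000, layout = layout)
}
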