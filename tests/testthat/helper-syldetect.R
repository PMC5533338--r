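# Shared fixtures, all generated in code.

# Small frame geometry with integer-millisecond frame times (rate 1000 Hz,
# hop 1 sample): frame k ends at sample 16 + (k-1), i.e. at (16 + k - 1) ms.
toy_config <- function() {
  frame_config(fft_size = 16, interval_ms = 1, sample_rate = 1000,
               band = c(0, 500), window_ms = 4)
}

# Build a frame_outputs object from plain lists; each clip is
# list(time_ms=, y=, canonical=) for a single-syllable detector.
make_outputs <- function(clips) {
  recs <- lapply(clips, function(cl) {
    list(Y = matrix(cl$y, nrow = 1), time_ms = cl$time_ms,
         end_sample = cl$time_ms, is_song = length(cl$canonical) > 0,
         canonical = as.numeric(cl$canonical))
  })
  structure(list(clips = recs, n_targets = 1L), class = "frame_outputs")
}

# A hand-built "energy in the newest frame" detector at the default frame
# geometry: one hidden unit whose input weights select the newest frame block
# of the (window-normalized, identity feature-normalized) recognition vector.
# Output ~ sum of the newest block's z-scores: positive while a sound starts,
# ~0 in silence. No training, so streaming tests are fast and deterministic.
hand_model <- function(threshold = 2, debounce_ms = 100,
                       config = frame_config()) {
  dim <- config$n_bins * config$n_frames
  w <- numeric(dim)
  w[(dim - config$n_bins + 1L):dim] <- 1e-4   # newest frame block
  params <- list(W0 = matrix(w, nrow = 1), b0 = 0,
                 W1 = matrix(1e4), b1 = 0)
  norm <- structure(list(mu = numeric(dim), sigma = rep(1, dim)),
                    class = "feature_norm")
  structure(
    list(params = params, norm = norm, config = config,
         thresholds = threshold, threshold_counts = NULL,
         cost = cost_config(), train = NULL, target_sd_ms = 2,
         debounce_ms = debounce_ms, history = NULL, val_mse = NA_real_,
         trainer = "hand-built", n_targets = 1L, corpus_id = "hand-model",
         format_version = 1L),
    class = "syllable_detector")
}

# short tone burst embedded in silence
tone_burst_clip <- function(burst_at_ms, dur_ms = 20, total_ms = 400,
                            freq = 3000, rate = 44100) {
  clip <- numeric(round(total_ms / 1000 * rate))
  n <- round(dur_ms / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  for (at in burst_at_ms) {
    k <- round(at / 1000 * rate)
    clip[k + seq_len(n)] <- sin(2 * pi * freq * t)
  }
  clip
}

# One small trained delta-syllable detector, shared across test files
# (reduced geometry: 30 ms window at a 3 ms frame interval).
tiny_model_env <- new.env(parent = emptyenv())
get_tiny_delta_fit <- function() {
  if (is.null(tiny_model_env$fit)) {
    corpus <- generate_delta_corpus(n_songs = 40, seed = 5)
    cfg <- frame_config(interval_ms = 3, window_ms = 30)
    fit <- syllable_detector(corpus, cfg,
                             train = train_config(max_iter = 120,
                                                  round_iter = 40, seed = 5))
    tiny_model_env$fit <- fit
    tiny_model_env$corpus <- corpus
  }
  list(fit = tiny_model_env$fit, corpus = tiny_model_env$corpus)
}

# random non-overlapping-window output trace for threshold tests
random_trace <- function(n_frames = 60, delta_t = 3) {
  time_ms <- seq_len(n_frames)
  n_ev <- sample(1:3, 1)
  repeat {
    ev <- sort(round(runif(n_ev, delta_t + 1, n_frames - delta_t - 1), 1))
    if (n_ev == 1 || all(diff(ev) >= 2 * delta_t + 1)) break
  }
  y <- runif(n_frames)
  list(time_ms = time_ms, y = y, canonical = ev)
}
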