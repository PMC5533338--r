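#' Fit a syllable detector to an aligned corpus
#'
#' The single fitting entry point of the package. From an aligned corpus of
#' songs (with canonical target times) and non-song clips it:
#' \enumerate{
#'   \item assembles the training matrix of window-normalized
#'     recognition-region vectors and the Gaussian-smoothed target matrix
#'     ([build_training_set()]);
#'   \item fits and applies the per-feature normalization
#'     ([fit_feature_norm()]);
#'   \item trains the two-layer perceptron against the smoothed targets with
#'     validation-based early stopping ([train_network()]);
#'   \item chooses one detection threshold per target syllable by exact cost
#'     minimization over the full training corpus ([optimal_threshold()]).
#' }
#'
#' @param corpus An `"annotated_corpus"` (see [generate_corpus()],
#'   [generate_delta_corpus()], [read_corpus()]).
#' @param config A [frame_config()]; defaults to the package defaults
#'   (256-point FFT, Hamming window, 1.5 ms requested frame interval,
#'   1–8 kHz band, 50 ms recognition window).
#' @param train A [train_config()].
#' @param cost A [cost_config()] (`c_n = 1`, `delta_t_ms = 10` by default).
#' @param target_sd_ms Gaussian target kernel SD, ms. Default 2.
#' @param debounce_ms Streaming refractory interval per syllable, ms.
#'   Default 100.
#' @return An object of class `"syllable_detector"`: network parameters,
#'   feature normalization, frame configuration, per-syllable thresholds,
#'   cost settings, training history and the training-corpus id.
#' @seealso [predict.syllable_detector()], [detect_file()],
#'   [evaluate_accuracy()], [ideal_timing()], [save_model()]
#' @examples
#' \donttest{
#' corpus <- generate_delta_corpus(n_songs = 60, seed = 1)
#' fit <- syllable_detector(corpus, train = train_config(max_iter = 120))
#' print(fit)
#' }
#' @export
syllable_detector <- function(corpus, config = frame_config(),
                              train = train_config(), cost = cost_config(),
                              target_sd_ms = 2, debounce_ms = 100) {
  stopifnot(inherits(corpus, "annotated_corpus"),
            inherits(config, "frame_config"),
            inherits(train, "train_config"),
            inherits(cost, "cost_config"))
  ts <- build_training_set(corpus, config, target_sd_ms)
  norm <- fit_feature_norm(ts$Xi)
  X <- apply_feature_norm(norm, ts$Xi)
  ts$Xi <- NULL
  fit <- train_network(X, ts$targets, train)
  n_targets <- nrow(ts$targets)
  Y_all <- nn_forward(fit$params, X)
  if (!is.matrix(Y_all)) Y_all <- matrix(Y_all, nrow = n_targets)
  rm(X)
  outputs <- .outputs_from_matrix(Y_all, ts$meta, corpus$canonical_times,
                                  n_targets)
  thresholds <- numeric(n_targets)
  threshold_counts <- vector("list", n_targets)
  for (k in seq_len(n_targets)) {
    th <- optimal_threshold(outputs, cost, k)
    thresholds[k] <- as.numeric(th)
    threshold_counts[[k]] <- attr(th, "counts")
  }
  structure(
    list(params = fit$params, norm = norm, config = config,
         thresholds = thresholds, threshold_counts = threshold_counts,
         cost = cost, train = train, target_sd_ms = target_sd_ms,
         debounce_ms = debounce_ms, history = fit$history,
         val_mse = fit$val_mse, trainer = fit$trainer,
         n_targets = n_targets, corpus_id = corpus$id,
         format_version = 1L),
    class = "syllable_detector")
}

#' @export
print.syllable_detector <- function(x, ...) {
  cat("Syllable detector\n")
  cat(sprintf("  targets     : %d syllable(s); thresholds %s\n", x$n_targets,
              paste(sprintf("%.4f", x$thresholds), collapse = ", ")))
  cat(sprintf("  network     : %d -> %d tanh -> %d linear\n",
              ncol(x$params$W0), nrow(x$params$W0), nrow(x$params$W1)))
  cat(sprintf("  frames      : %d-pt FFT, hop %d samples (%.4f ms), %d-frame window, %g-%g Hz\n",
              x$config$fft_size, x$config$hop, x$config$effective_interval_ms,
              x$config$n_frames, x$config$band[1], x$config$band[2]))
  cat(sprintf("  training    : %s; validation MSE %.3g\n", x$trainer, x$val_mse))
  cat(sprintf("  trained on  : %s\n", x$corpus_id))
  invisible(x)
}

#' @export
summary.syllable_detector <- function(object, ...) {
  s <- list(model = object,
            n_params = length(.pack_params(object$params)),
            rounds = if (is.null(object$history)) 0L else nrow(object$history),
            threshold_counts = object$threshold_counts)
  class(s) <- "summary.syllable_detector"
  s
}

#' @export
print.summary.syllable_detector <- function(x, ...) {
  print(x$model)
  cat(sprintf("  parameters  : %d trainable weights, %d optimization rounds\n",
              x$n_params, x$rounds))
  for (k in seq_along(x$threshold_counts)) {
    ct <- x$threshold_counts[[k]]
    cat(sprintf("  syllable %d  : training-corpus TP %d, FN %d, FP frames %d at threshold %.4f\n",
                k, ct[["TP"]], ct[["FN"]], ct[["FP"]], x$model$thresholds[k]))
  }
  invisible(x)
}

#' @export
coef.syllable_detector <- function(object, ...) {
  object$params
}

#' Predict detector outputs or detection events
#'
#' @param object A fitted `"syllable_detector"`.
#' @param newdata Audio to score: a numeric sample vector (assumed at the
#'   model rate), a list with `samples` and `rate`, a path to a WAV file, or
#'   an `"annotated_corpus"`.
#' @param type `"frames"` for the offline per-frame network outputs (the
#'   un-de-bounced ideal path), `"events"` for de-bounced streaming detection
#'   events.
#' @param chunk_samples Chunk size for the streaming path. Default 32.
#' @param ... Unused.
#' @return For `type = "frames"`: a list with `time_ms` and `outputs`
#'   (`n_targets x n_frames`) for single clips, or a `"frame_outputs"` object
#'   for a corpus. For `type = "events"`: a data frame of detection events
#'   (see [detect_file()]).
#' @export
predict.syllable_detector <- function(object, newdata,
                                      type = c("frames", "events"),
                                      chunk_samples = 32, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "annotated_corpus")) {
    if (type == "frames") return(corpus_outputs(object, newdata))
    stop("events prediction expects a single clip; use detect_file() per clip")
  }
  if (is.character(newdata)) newdata <- read_wav(newdata)
  samples <- .as_samples(newdata, object$config$sample_rate)
  if (type == "frames") {
    cc <- .clip_columns(samples, object$config)
    Y <- nn_forward(object$params, apply_feature_norm(object$norm, cc$X))
    if (!is.matrix(Y)) Y <- matrix(Y, nrow = object$n_targets)
    list(time_ms = cc$time_ms, end_sample = cc$end_sample, outputs = Y)
  } else {
    state <- detector_state(object)
    feed(state, samples, chunk_samples = chunk_samples)
  }
}

#' Plot the detector's response to a clip
#'
#' Draws the per-frame network output for each target syllable over time,
#' with the detection threshold as a dashed line.
#'
#' @param x A `"syllable_detector"`.
#' @param clip Audio clip (vector, `list(samples, rate)` or WAV path).
#' @param ... Passed to [graphics::matplot()].
#' @return The frame outputs, invisibly.
#' @export
plot.syllable_detector <- function(x, clip, ...) {
  pr <- predict(x, clip, type = "frames")
  graphics::matplot(pr$time_ms, t(pr$outputs), type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "network output", ...)
  graphics::abline(h = x$thresholds, lty = 2,
                   col = seq_len(x$n_targets))
  invisible(pr)
}

# ---- model file -------------------------------------------------------------

# Doubles are serialized as "%.17g" strings: 17 significant digits round-trip
# IEEE doubles exactly, which the bit-for-bit save/load contract requires.
.ser_num <- function(x) sprintf("%.17g", as.numeric(x))
.ser_mat <- function(m) list(dim = dim(m), values = .ser_num(m))
.de_num <- function(s) as.numeric(s)
.de_mat <- function(l) matrix(as.numeric(l$values), l$dim[1], l$dim[2])

#' Save a fitted detector to a model file
#'
#' Writes a self-describing JSON container holding the network weights, both
#' normalization stages, the frame configuration, thresholds and cost
#' settings, with a format version. Numeric payloads are stored at 17
#' significant digits, so [load_model()] reproduces the detector bit-for-bit.
#'
#' @param model A `"syllable_detector"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "syllable_detector"))
  obj <- list(
    container = "syldetect-model", format_version = model$format_version,
    trainer = model$trainer, n_targets = model$n_targets,
    config = list(fft_size = model$config$fft_size,
                  interval_ms = .ser_num(model$config$interval_ms),
                  sample_rate = .ser_num(model$config$sample_rate),
                  band = .ser_num(model$config$band),
                  window_ms = .ser_num(model$config$window_ms)),
    params = list(W0 = .ser_mat(model$params$W0), b0 = .ser_num(model$params$b0),
                  W1 = .ser_mat(model$params$W1), b1 = .ser_num(model$params$b1)),
    norm = list(mu = .ser_num(model$norm$mu), sigma = .ser_num(model$norm$sigma)),
    thresholds = .ser_num(model$thresholds),
    cost = list(c_n = .ser_num(model$cost$c_n),
                delta_t_ms = .ser_num(model$cost$delta_t_ms)),
    target_sd_ms = .ser_num(model$target_sd_ms),
    debounce_ms = .ser_num(model$debounce_ms),
    val_mse = .ser_num(model$val_mse),
    corpus_id = model$corpus_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Load a detector model file
#'
#' @param path Path written by [save_model()].
#' @return A `"syllable_detector"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("corrupted or truncated model file: ", path,
                         " (", conditionMessage(e), ")")
                  })
  if (!identical(obj$container, "syldetect-model")) {
    stop("not a syldetect model file: ", path)
  }
  if (!identical(as.integer(obj$format_version), 1L)) {
    stop("unsupported model format version ", obj$format_version,
         " in ", path)
  }
  config <- frame_config(fft_size = obj$config$fft_size,
                         interval_ms = .de_num(obj$config$interval_ms),
                         sample_rate = .de_num(obj$config$sample_rate),
                         band = .de_num(obj$config$band),
                         window_ms = .de_num(obj$config$window_ms))
  params <- list(W0 = .de_mat(obj$params$W0), b0 = .de_num(obj$params$b0),
                 W1 = .de_mat(obj$params$W1), b1 = .de_num(obj$params$b1))
  structure(
    list(params = params,
         norm = structure(list(mu = .de_num(obj$norm$mu),
                               sigma = .de_num(obj$norm$sigma)),
                          class = "feature_norm"),
         config = config, thresholds = .de_num(obj$thresholds),
         threshold_counts = NULL,
         cost = cost_config(.de_num(obj$cost$c_n),
                            .de_num(obj$cost$delta_t_ms)),
         train = NULL, target_sd_ms = .de_num(obj$target_sd_ms),
         debounce_ms = .de_num(obj$debounce_ms), history = NULL,
         val_mse = .de_num(obj$val_mse), trainer = obj$trainer,
         n_targets = as.integer(obj$n_targets), corpus_id = obj$corpus_id,
         format_version = 1L),
    class = "syllable_detector")
}
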