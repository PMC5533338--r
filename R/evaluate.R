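#' Per-frame detection accuracy on a held-out corpus
#'
#' Runs the offline, un-de-bounced outputs over every clip and scores them at
#' the model's stored thresholds with the per-frame definitions used for
#' threshold optimization: an event is a true positive if any frame within
#' `+/- delta_t_ms` of its canonical time is above threshold; every
#' above-threshold frame inside no acceptance window is one false-positive
#' frame. The true-positive rate is `100 * TP / n_events`; the
#' false-positive rate is `100 * FP / n_negative_frames`, where the
#' denominator counts all frames outside every acceptance window — a
#' definition that remains meaningful on unsegmented streams of calls and
#' cage noise.
#'
#' @param model A fitted `"syllable_detector"`.
#' @param corpus An `"annotated_corpus"`, disjoint from the training corpus
#'   (asserted via corpus ids).
#' @param cost A [cost_config()]; defaults to the model's.
#' @param allow_training_corpus Set `TRUE` to skip the disjointness check
#'   (used internally for training-set diagnostics).
#' @return An object of class `"accuracy_report"`: data frame with one row
#'   per syllable (`tp`, `fn`, `fp`, `n_events`, `n_negative_frames`,
#'   `tp_pct`, `fp_pct`; `tp_pct` is `NA` when the corpus holds no events).
#' @export
evaluate_accuracy <- function(model, corpus, cost = model$cost,
                              allow_training_corpus = FALSE) {
  stopifnot(inherits(model, "syllable_detector"),
            inherits(corpus, "annotated_corpus"))
  if (length(corpus$songs) + length(corpus$nonsong) == 0) {
    stop("cannot evaluate an empty corpus")
  }
  if (!allow_training_corpus && identical(corpus$id, model$corpus_id)) {
    stop("evaluation corpus '", corpus$id,
         "' is the corpus the model was trained on; accuracy must be ",
         "measured on held-out data")
  }
  outputs <- corpus_outputs(model, corpus)
  accuracy_from_outputs(outputs, model$thresholds, cost)
}

#' Score precomputed frame outputs at given thresholds
#'
#' The counting core of [evaluate_accuracy()], exposed so that constructed
#' output traces can be scored directly.
#'
#' @param outputs A `"frame_outputs"` object.
#' @param thresholds Numeric vector, one threshold per syllable.
#' @param cost A [cost_config()].
#' @return An `"accuracy_report"` (see [evaluate_accuracy()]).
#' @export
accuracy_from_outputs <- function(outputs, thresholds, cost) {
  rows <- lapply(seq_len(outputs$n_targets), function(k) {
    ce <- count_errors(outputs, thresholds[k], cost, k)
    n_events <- ce[["TP"]] + ce[["FN"]]
    n_neg <- .n_negative_frames(outputs, cost$delta_t_ms, k)
    data.frame(syllable = k, tp = ce[["TP"]], fn = ce[["FN"]], fp = ce[["FP"]],
               n_events = n_events, n_negative_frames = n_neg,
               tp_pct = if (n_events > 0) 100 * ce[["TP"]] / n_events
                        else NA_real_,
               fp_pct = if (n_neg > 0) 100 * ce[["FP"]] / n_neg else 0)
  })
  structure(do.call(rbind, rows), class = c("accuracy_report", "data.frame"))
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Per-frame accuracy\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  syllable %d: TP %.2f%% (%d/%d events), FP %.4f%% (%d/%d frames)\n",
                x$syllable[i],
                if (is.na(x$tp_pct[i])) NaN else x$tp_pct[i],
                x$tp[i], x$n_events[i], x$fp_pct[i], x$fp[i],
                x$n_negative_frames[i]))
  }
  invisible(x)
}

#' Latency and jitter from matched detection events
#'
#' Matches each canonical event time to the nearest detection within
#' `+/- delta_t_ms` (greedy one-to-one, canonical events in time order) and
#' summarizes the signed latencies `trigger - canonical`. Negative latencies
#' are legitimate: a detector's evidence often crosses threshold slightly
#' before its response peaks. Jitter is the sample standard deviation of the
#' matched latencies; undetected events contribute no latency.
#'
#' @param event_times_ms Detection trigger times, ms, on the same clock as
#'   `canonical_ms`.
#' @param canonical_ms Canonical (ground-truth) event times, ms.
#' @param delta_t_ms Acceptance half-window, ms.
#' @return An object of class `"timing_report"`: list with `latencies_ms`,
#'   `latency_mean_ms`, `jitter_ms`, `n_events`, `n_detected`.
#' @export
measure_timing <- function(event_times_ms, canonical_ms, delta_t_ms = 10) {
  ev <- sort(as.numeric(event_times_ms))
  used <- logical(length(ev))
  lat <- numeric(0)
  for (cn in sort(as.numeric(canonical_ms))) {
    cand <- which(!used & abs(ev - cn) <= delta_t_ms)
    if (length(cand)) {
      pick <- cand[which.min(abs(ev[cand] - cn))]
      used[pick] <- TRUE
      lat <- c(lat, ev[pick] - cn)
    }
  }
  structure(list(latencies_ms = lat,
                 latency_mean_ms = if (length(lat)) mean(lat) else NA_real_,
                 jitter_ms = if (length(lat) > 1) stats::sd(lat) else NA_real_,
                 n_events = length(canonical_ms), n_detected = length(lat)),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("Timing: %d/%d events detected; latency %.3f ms, jitter %.3f ms\n",
              x$n_detected, x$n_events, x$latency_mean_ms, x$jitter_ms))
  invisible(x)
}

#' Ideal-detector timing on a corpus
#'
#' The ideal detector is the offline, zero-buffer evaluation path: frames are
#' computed at exact hop positions with no audio-buffer or scheduling delays,
#' and for each canonical event the trigger is the end time of the first
#' above-threshold frame inside the acceptance window. The resulting latency
#' and jitter reflect only what is inherent in the algorithm — the FFT size,
#' the frame hop, and the width of the Gaussian target kernel — and so bound
#' what any live implementation of the same model can achieve.
#'
#' @param model A fitted `"syllable_detector"`.
#' @param corpus An `"annotated_corpus"`.
#' @param delta_t_ms Acceptance half-window; defaults to the model's.
#' @return A list of `"timing_report"` objects, one per target syllable.
#' @export
ideal_timing <- function(model, corpus, delta_t_ms = model$cost$delta_t_ms) {
  outputs <- corpus_outputs(model, corpus)
  lapply(seq_len(model$n_targets), function(k) {
    lat <- numeric(0)
    n_events <- 0L
    for (cl in outputs$clips) {
      for (e in cl$canonical) {
        n_events <- n_events + 1L
        w <- which(abs(cl$time_ms - e) <= delta_t_ms &
                     cl$Y[k, ] > model$thresholds[k])
        if (length(w)) lat <- c(lat, cl$time_ms[w[1L]] - e)
      }
    }
    structure(list(latencies_ms = lat,
                   latency_mean_ms = if (length(lat)) mean(lat) else NA_real_,
                   jitter_ms = if (length(lat) > 1) stats::sd(lat)
                               else NA_real_,
                   n_events = n_events, n_detected = length(lat)),
              class = "timing_report")
  })
}

#' Latency/jitter/accuracy trade-off across frame intervals
#'
#' Trains one detector per requested frame interval on the same corpus (same
#' seeds throughout, so rows are reproducible) and reports ideal-detector
#' timing plus per-frame accuracy. Shorter frame intervals generally lower
#' both latency and jitter at the price of training time.
#'
#' @param corpus Training `"annotated_corpus"`.
#' @param intervals_ms Numeric vector of requested frame intervals, ms.
#' @param eval_corpus Corpus for accuracy/timing; defaults to the training
#'   corpus (accuracy then is a training-set diagnostic).
#' @param config Base [frame_config()] supplying FFT size, band, window.
#' @param train,cost,target_sd_ms Passed to [syllable_detector()].
#' @param syllable Syllable index to report.
#' @return Data frame with one row per interval: `interval_ms`,
#'   `effective_interval_ms`, `latency_ms`, `jitter_ms`, `tp_pct`, `fp_pct`.
#' @export
sweep_frame_interval <- function(corpus, intervals_ms, eval_corpus = NULL,
                                 config = frame_config(),
                                 train = train_config(), cost = cost_config(),
                                 target_sd_ms = 2, syllable = 1) {
  rows <- lapply(intervals_ms, function(iv) {
    cfg <- frame_config(fft_size = config$fft_size, interval_ms = iv,
                        sample_rate = config$sample_rate, band = config$band,
                        window_ms = config$window_ms)
    model <- syllable_detector(corpus, cfg, train = train, cost = cost,
                               target_sd_ms = target_sd_ms)
    ec <- if (is.null(eval_corpus)) corpus else eval_corpus
    acc <- evaluate_accuracy(model, ec,
                             allow_training_corpus = is.null(eval_corpus))
    tim <- ideal_timing(model, ec)[[syllable]]
    data.frame(interval_ms = iv,
               effective_interval_ms = cfg$effective_interval_ms,
               latency_ms = tim$latency_mean_ms, jitter_ms = tim$jitter_ms,
               tp_pct = acc$tp_pct[syllable], fp_pct = acc$fp_pct[syllable])
  })
  do.call(rbind, rows)
}
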