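#' Detection cost configuration
#'
#' @param c_n Relative cost of a false negative versus a false positive
#'   (`cost = FP + c_n * FN`). Default 1.
#' @param delta_t_ms Acceptance half-window in ms: a true event at `t*` counts
#'   as detected if any above-threshold frame lies within `t* +/- delta_t_ms`.
#'   Default 10.
#' @return An object of class `"cost_config"`.
#' @export
cost_config <- function(c_n = 1, delta_t_ms = 10) {
  if (c_n <= 0) stop("c_n must be positive")
  if (delta_t_ms < 0) stop("delta_t_ms must be non-negative")
  structure(list(c_n = c_n, delta_t_ms = delta_t_ms), class = "cost_config")
}

#' Raw network outputs for every frame of a corpus
#'
#' Runs the offline (un-de-bounced) detection path — frame computation,
#' recognition-window assembly, both normalizations, forward pass — over every
#' clip of a corpus. This is the input to threshold optimization and to
#' per-frame accuracy evaluation.
#'
#' @param model A fitted [syllable_detector()].
#' @param corpus An `"annotated_corpus"` at the model's sample rate.
#' @return An object of class `"frame_outputs"`: list of per-clip records
#'   (`Y` = `n_targets x n_frames` output matrix, `time_ms`, `is_song`,
#'   `canonical` = that song's canonical times), plus `n_targets`.
#' @export
corpus_outputs <- function(model, corpus) {
  stopifnot(inherits(model, "syllable_detector"),
            inherits(corpus, "annotated_corpus"))
  if (corpus$rate != model$config$sample_rate) {
    stop("corpus rate ", corpus$rate, " Hz does not match model rate ",
         model$config$sample_rate, " Hz")
  }
  clips <- c(corpus$songs, corpus$nonsong)
  n_song <- length(corpus$songs)
  recs <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    cc <- .clip_columns(clips[[i]], model$config)
    Y <- nn_forward(model$params, apply_feature_norm(model$norm, cc$X))
    if (!is.matrix(Y)) Y <- matrix(Y, nrow = model$n_targets)
    recs[[i]] <- list(Y = Y, time_ms = cc$time_ms,
                      end_sample = cc$end_sample, is_song = i <= n_song,
                      canonical = if (i <= n_song)
                        as.numeric(corpus$canonical_times[i, ]) else numeric(0))
  }
  structure(list(clips = recs, n_targets = model$n_targets),
            class = "frame_outputs")
}

# Assemble a frame_outputs object from precomputed outputs + column metadata
# (used during fitting so the training matrix is not recomputed).
.outputs_from_matrix <- function(Y_all, meta, canonical_times, n_targets) {
  recs <- list()
  for (cl in unique(meta$clip)) {
    sel <- meta$clip == cl
    is_song <- meta$is_song[sel][1]
    recs[[length(recs) + 1L]] <- list(
      Y = Y_all[, sel, drop = FALSE],
      time_ms = meta$time_ms[sel], end_sample = meta$end_sample[sel],
      is_song = is_song,
      canonical = if (is_song) as.numeric(canonical_times[cl, ])
                  else numeric(0))
  }
  structure(list(clips = recs, n_targets = n_targets),
            class = "frame_outputs")
}

#' Per-frame error counts at a given threshold
#'
#' A true event at `t*` is a true positive if at least one frame with output
#' strictly above the threshold lies within `t* +/- delta_t_ms`, otherwise a
#' false negative; when acceptance windows overlap, one above-threshold frame
#' can satisfy at most one event (greedy earliest-frame assignment in time
#' order). Every above-threshold frame lying inside no acceptance window
#' counts as one false-positive frame. Counts use the raw, un-de-bounced
#' outputs.
#'
#' @param outputs A `"frame_outputs"` object.
#' @param threshold Scalar detection threshold.
#' @param cost A [cost_config()] (supplies `delta_t_ms`).
#' @param syllable Target syllable index.
#' @return Named numeric vector `c(FP, FN, TP)`.
#' @export
count_errors <- function(outputs, threshold, cost, syllable = 1) {
  dt <- cost$delta_t_ms
  FP <- 0L; FN <- 0L; TP <- 0L
  for (cl in outputs$clips) {
    t_above <- cl$time_ms[cl$Y[syllable, ] > threshold]
    ev <- sort(cl$canonical)
    if (length(ev)) {
      used <- logical(length(t_above))
      for (e in ev) {
        elig <- which(!used & abs(t_above - e) <= dt)
        if (length(elig)) {
          TP <- TP + 1L
          used[elig[1L]] <- TRUE
        } else {
          FN <- FN + 1L
        }
      }
      if (length(t_above)) {
        inside <- vapply(t_above,
                         function(t) any(abs(t - ev) <= dt), logical(1))
        FP <- FP + sum(!inside)
      }
    } else {
      FP <- FP + length(t_above)
    }
  }
  c(FP = FP, FN = FN, TP = TP)
}

# frames lying inside no acceptance window (false-positive denominator)
.n_negative_frames <- function(outputs, delta_t_ms, syllable = 1) {
  total <- 0L
  for (cl in outputs$clips) {
    if (length(cl$canonical)) {
      inside <- rep(FALSE, length(cl$time_ms))
      for (e in cl$canonical) {
        inside <- inside | abs(cl$time_ms - e) <= delta_t_ms
      }
      total <- total + sum(!inside)
    } else {
      total <- total + length(cl$time_ms)
    }
  }
  total
}

#' Optimal detection threshold for one syllable
#'
#' Minimizes `FP(theta) + c_n * FN(theta)` over the training outputs by exact
#' linear search. The cost is piecewise constant, changing only where `theta`
#' crosses an observed output value, so the candidate grid of midpoints
#' between consecutive sorted unique outputs (plus one point above the
#' maximum) is exhaustive. Ties are broken toward the largest minimizing
#' threshold — large portions of the cost surface are flat, and a higher
#' threshold is conservative against false positives on unseen data.
#'
#' @param outputs A `"frame_outputs"` object (training corpus).
#' @param cost A [cost_config()].
#' @param syllable Target syllable index.
#' @return The scalar threshold, with attributes `cost` (minimum achieved)
#'   and `counts` (the `c(FP, FN, TP)` at the optimum).
#' @export
optimal_threshold <- function(outputs, cost, syllable = 1) {
  n_events <- sum(vapply(outputs$clips,
                         function(cl) length(cl$canonical), integer(1)))
  if (n_events < 1) stop("threshold optimization needs at least one event")
  vals <- unlist(lapply(outputs$clips, function(cl) cl$Y[syllable, ]))
  u <- sort(unique(vals))
  cand <- if (length(u) > 1) {
    c((u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  } else {
    u + 1
  }
  overlap <- any(vapply(outputs$clips, function(cl) {
    length(cl$canonical) > 1 &&
      any(diff(sort(cl$canonical)) < 2 * cost$delta_t_ms)
  }, logical(1)))

  if (!overlap) {
    dt <- cost$delta_t_ms
    ev_max <- c(); neg <- c()
    for (cl in outputs$clips) {
      y <- cl$Y[syllable, ]
      if (length(cl$canonical)) {
        inside <- rep(FALSE, length(y))
        for (e in cl$canonical) {
          w <- abs(cl$time_ms - e) <= dt
          inside <- inside | w
          ev_max <- c(ev_max, if (any(w)) max(y[w]) else -Inf)
        }
        neg <- c(neg, y[!inside])
      } else {
        neg <- c(neg, y)
      }
    }
    sneg <- sort(neg)
    sev <- sort(ev_max)
    fp <- length(sneg) - findInterval(cand, sneg)
    fn <- findInterval(cand, sev)
    costs <- fp + cost$c_n * fn
  } else {
    costs <- vapply(cand, function(th) {
      ce <- count_errors(outputs, th, cost, syllable)
      ce[["FP"]] + cost$c_n * ce[["FN"]]
    }, numeric(1))
  }
  best <- max(cand[costs == min(costs)])
  counts <- count_errors(outputs, best, cost, syllable)
  structure(best, cost = min(costs), counts = counts)
}
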