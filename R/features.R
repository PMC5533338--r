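#' Per-window z-score normalization
#'
#' First of the two normalization stages: each recognition-region vector is
#' z-scored over its own elements, so that overall level differences (bird
#' position, gain) are removed and only the spectro-temporal pattern remains.
#' The sample (n-1) standard deviation convention is used throughout the
#' package. Exactly constant windows — e.g. digital silence — map to the zero
#' vector: zero is the only scale-free choice and keeps silence maximally
#' distinct from structured sound.
#'
#' @param x Numeric vector (one recognition window) or matrix (one window per
#'   column).
#' @return Same shape as `x`; each non-constant window has mean 0 and sample
#'   SD 1.
#' @export
window_normalize <- function(x) {
  if (is.matrix(x)) .window_normalize_cols(x)
  else as.vector(.window_normalize_cols(matrix(x, ncol = 1)))
}

# Column-wise z-scoring. The streaming detector wraps its single window in a
# one-column matrix and calls this same function, so the training and runtime
# arithmetic is identical summation-for-summation.
.window_normalize_cols <- function(M) {
  n <- nrow(M)
  m <- colMeans(M)
  Mc <- M - rep(m, each = n)
  s <- sqrt(colSums(Mc * Mc) / (n - 1))
  const <- colSums(M != rep(M[1L, ], each = n)) == 0L  # exactly constant
  s[const] <- 1
  out <- Mc / rep(s, each = n)
  if (any(const)) out[, const] <- 0
  out
}

#' Fit the per-feature normalization
#'
#' Second normalization stage: each element of the window-normalized
#' recognition vector (each row of the training matrix) is z-scored across
#' the whole training set, so every input feature reaches the network with
#' comparable range. The fitted transform is stored inside the detector and
#' applied unchanged to unseen data at run time.
#'
#' @param Xi Window-normalized training matrix (features x columns), at least
#'   two columns.
#' @param sigma_floor Lower bound for the per-row SD, guarding rows that are
#'   constant across the corpus.
#' @return An object of class `"feature_norm"` with vectors `mu` and `sigma`.
#' @export
fit_feature_norm <- function(Xi, sigma_floor = 1e-8) {
  if (!is.matrix(Xi) || ncol(Xi) < 2) {
    stop("feature normalization needs a matrix with at least 2 columns")
  }
  n <- ncol(Xi)
  mu <- rowMeans(Xi)
  sigma <- sqrt(rowSums((Xi - mu)^2) / (n - 1))
  sigma <- pmax(sigma, sigma_floor)
  structure(list(mu = mu, sigma = sigma), class = "feature_norm")
}

#' Apply a fitted feature normalization
#'
#' @param norm A `"feature_norm"` from [fit_feature_norm()].
#' @param x Vector or matrix (features x columns) at the window-normalized
#'   stage.
#' @return Feature-normalized vector/matrix of the same shape.
#' @export
apply_feature_norm <- function(norm, x) {
  if (is.matrix(x)) (x - norm$mu) / norm$sigma
  else (x - norm$mu) / norm$sigma
}

# Window-normalized recognition vectors for one clip.
# Returns X ((n_bins * n_frames) x n_cols), with column j spanning frames
# j..j+n_frames-1 (oldest -> newest frame blocks), plus frame-end metadata for
# the newest frame of each column. This is the single assembly path shared by
# training-set construction and offline prediction.
.clip_columns <- function(samples, config) {
  fr <- .frames_of_clip(samples, config)
  K <- ncol(fr$power)
  nf <- config$n_frames
  if (K < nf) {
    stop("clip too short: ", K, " frames but the recognition window needs ",
         nf)
  }
  n_cols <- K - nf + 1L
  sel <- as.vector(outer(seq_len(nf), 0:(n_cols - 1L), "+"))
  X <- fr$power[, sel, drop = FALSE]
  dim(X) <- c(config$n_bins * nf, n_cols)
  X <- .window_normalize_cols(X)
  end_sample <- fr$end_sample[nf:K]
  list(X = X, end_sample = end_sample,
       time_ms = end_sample / config$sample_rate * 1000)
}

# Gaussian target row(s) for one song clip. The kernel is centred causally:
# on the end time of the first frame at or after t*, so the detector is never
# asked to announce the target before the audio through t* has been seen.
# With an on-grid centre the peak frame carries exactly 1.
.clip_targets <- function(time_ms, canonical, target_sd_ms, clip_label) {
  n_t <- length(canonical)
  Y <- matrix(0, n_t, length(time_ms))
  for (k in seq_len(n_t)) {
    ts <- canonical[k]
    if (ts <= 0 || ts > max(time_ms)) {
      stop("target time ", round(ts, 3), " ms of ", clip_label,
           " has no spectrogram frame at or after it ",
           "(usable frames end at ", round(max(time_ms), 3), " ms)")
    }
    at_or_after <- which(time_ms >= ts)
    if (length(at_or_after) == 0) {
      stop("target time ", round(ts, 3), " ms of ", clip_label,
           " lies beyond the last usable frame")
    }
    centre <- time_ms[at_or_after[1L]]
    d <- time_ms - centre
    y <- exp(-d^2 / (2 * target_sd_ms^2))
    y[abs(d) > 3 * target_sd_ms] <- 0
    Y[k, ] <- y
  }
  Y
}

#' Assemble the training matrix and smoothed target matrix
#'
#' Every clip of the corpus contributes one recognition-region column per
#' spectrogram frame (frames before the recognition window first fills are
#' skipped). Columns are window-normalized; the feature normalization is
#' fitted later, by the detector, on this matrix. Target rows hold a Gaussian
#' kernel of SD `target_sd_ms` around each song's canonical time, truncated at
#' 3 SD, with the peak frame carrying exactly 1; spreading the target in time
#' keeps near-identical neighbouring frames from receiving contradictory
#' labels. All non-song columns, and song columns outside the kernel support,
#' carry 0 and act as negative examples.
#'
#' @param corpus An `"annotated_corpus"`.
#' @param config A [frame_config()]; its sample rate must match the corpus.
#' @param target_sd_ms Gaussian target SD in ms. Default 2.
#' @return A list with `Xi` (features x columns training matrix,
#'   window-normalized), `targets` (`n_targets x columns`), and `meta`
#'   (data frame: `clip`, `is_song`, `end_sample`, `time_ms` per column).
#' @export
build_training_set <- function(corpus, config, target_sd_ms = 2) {
  stopifnot(inherits(corpus, "annotated_corpus"))
  if (corpus$rate != config$sample_rate) {
    stop("corpus rate ", corpus$rate, " Hz does not match configuration rate ",
         config$sample_rate, " Hz")
  }
  n_t <- ncol(corpus$canonical_times)
  clips <- c(corpus$songs, corpus$nonsong)
  n_song <- length(corpus$songs)
  Xs <- vector("list", length(clips))
  Ys <- vector("list", length(clips))
  meta <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    cc <- .clip_columns(clips[[i]], config)
    Xs[[i]] <- cc$X
    if (i <= n_song) {
      Ys[[i]] <- .clip_targets(cc$time_ms, corpus$canonical_times[i, ],
                               target_sd_ms, sprintf("song clip %d", i))
    } else {
      Ys[[i]] <- matrix(0, n_t, ncol(cc$X))
    }
    meta[[i]] <- data.frame(clip = i, is_song = i <= n_song,
                            end_sample = cc$end_sample, time_ms = cc$time_ms)
  }
  list(Xi = do.call(cbind, Xs), targets = do.call(cbind, Ys),
       meta = do.call(rbind, meta))
}
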