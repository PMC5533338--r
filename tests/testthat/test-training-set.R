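test_that("window normalization z-scores each window with the n-1 convention", {
  x <- c(0, 1, 2, 3, 7, 11)
  z <- window_normalize(x)
  expect_equal(z, (x - mean(x)) / sd(x))   # independent arithmetic
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  expect_identical(window_normalize(rep(3.7, 10)), numeric(10))
  expect_identical(window_normalize(numeric(10)), numeric(10))

  M <- cbind(x, rep(2.5, 6), rnorm(6))
  Z <- window_normalize(M)
  expect_equal(Z[, 1], z)
  expect_identical(Z[, 2], numeric(6))
  expect_equal(colMeans(Z)[3], 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("feature normalization fixes the sample-SD convention per row", {
  a <- 1.2; b <- 4.6
  Xi <- rbind(c(a, b), c(-1, 1))
  fn <- fit_feature_norm(Xi, sigma_floor = 1e-8)
  expect_equal(fn$mu[1], (a + b) / 2)
  expect_equal(fn$sigma[1], abs(a - b) / sqrt(2))  # sample (n-1) convention
  expect_equal(fn$sigma[2], sqrt(2))

  set.seed(2)
  X <- matrix(rnorm(50 * 40), 50, 40)
  fn2 <- fit_feature_norm(X)
  Xn <- apply_feature_norm(fn2, X)
  expect_equal(unname(apply(Xn, 1, mean)), numeric(50), tolerance = 1e-10)
  expect_equal(unname(apply(Xn, 1, sd)), rep(1, 50), tolerance = 1e-10)

  # rows constant across the corpus are floored, not divided by zero
  Xc <- rbind(rep(5, 10), rnorm(10))
  expect_equal(fit_feature_norm(Xc)$sigma[1], 1e-8)
  expect_error(fit_feature_norm(matrix(1:5, ncol = 1)), "2 columns")
})

test_that("training matrix geometry counts one column per usable frame", {
  corpus <- generate_corpus(zebra_finch_spec(n_songs = 2, n_nonsong = 2,
                                             seed = 4))
  cfg <- frame_config()
  ts <- build_training_set(corpus, cfg)
  frames_per_clip <- (length(corpus$songs[[1]]) - cfg$fft_size) %/% cfg$hop + 1
  expect_equal(ncol(ts$Xi), 4 * (frames_per_clip - cfg$n_frames + 1))
  expect_equal(nrow(ts$Xi), cfg$n_bins * cfg$n_frames)
  expect_equal(nrow(ts$meta), ncol(ts$Xi))
  expect_identical(dim(ts$targets), c(1L, ncol(ts$Xi)))
  # non-song columns are all-zero targets
  expect_true(all(ts$targets[, !ts$meta$is_song] == 0))
})

test_that("Gaussian targets peak at 1 on the target frame and truncate at 3 SD", {
  # toy geometry: frame k ends at (16 + k - 1) ms exactly
  cfg <- toy_config()
  clip <- rnorm(50)
  corpus <- structure(
    list(songs = list(clip), nonsong = list(),
         canonical_times = matrix(25, 1, 1), rate = 1000,
         nonsong_kinds = character(0), spec = NULL, id = "toy"),
    class = "annotated_corpus")
  ts <- build_training_set(corpus, cfg, target_sd_ms = 2)
  tms <- ts$meta$time_ms
  expect_equal(ts$targets[1, tms == 25], 1)                  # peak exactly 1
  expect_equal(ts$targets[1, tms == 27], exp(-1 / 2))        # t* + sigma
  expect_equal(ts$targets[1, tms == 23], exp(-1 / 2))
  expect_equal(ts$targets[1, tms == 31], exp(-4.5))          # 3 sigma edge
  expect_true(all(ts$targets[1, abs(tms - 25) > 6] == 0))    # truncated

  # an off-grid target centres causally on the next frame
  corpus$canonical_times <- matrix(24.5, 1, 1)
  ts2 <- build_training_set(corpus, cfg, target_sd_ms = 2)
  expect_equal(ts2$targets[1, tms == 25], 1)
  expect_equal(ts2$targets[1, tms == 24], exp(-1 / 8))

  corpus$canonical_times <- matrix(200, 1, 1)
  expect_error(build_training_set(corpus, cfg), "song clip 1")
})

test_that("training vectors equal the streaming assembly bit-for-bit", {
  cfg <- frame_config(interval_ms = 3, window_ms = 30)
  clip <- tone_burst_clip(60, total_ms = 120)
  cc <- syldetect:::.clip_columns(clip, cfg)

  # re-assemble by simulating the spectral ring frame by frame
  ring <- matrix(0, cfg$n_bins, cfg$n_frames)
  filled <- 0
  j <- 0
  n_frames_total <- (length(clip) - cfg$fft_size) %/% cfg$hop + 1
  for (k in seq_len(n_frames_total)) {
    win <- clip[(1 + (k - 1) * cfg$hop):((k - 1) * cfg$hop + cfg$fft_size)]
    ring <- cbind(ring[, -1, drop = FALSE], compute_frame(win, cfg))
    filled <- min(filled + 1, cfg$n_frames)
    if (filled == cfg$n_frames) {
      j <- j + 1
      xi <- syldetect:::.window_normalize_cols(
        matrix(as.vector(ring), ncol = 1))
      expect_identical(as.vector(xi), cc$X[, j])
    }
  }
  expect_equal(j, ncol(cc$X))

  # the feature-normalization stage is also identical vector vs matrix
  fn <- fit_feature_norm(cc$X)
  Xn <- apply_feature_norm(fn, cc$X)
  expect_identical(apply_feature_norm(fn, cc$X[, 3]), Xn[, 3])
})
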