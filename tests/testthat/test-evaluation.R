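test_that("latency follows the canonical-vs-trigger worked example", {
  # canonical event at 200 ms, detector fires at 203 ms -> latency 3 ms
  tr <- measure_timing(203, 200, delta_t_ms = 10)
  expect_equal(tr$latencies_ms, 3)
  expect_equal(tr$latency_mean_ms, 3)
  expect_equal(tr$n_detected, 1)
})

test_that("timing summaries reduce to direct mean/SD computations", {
  exact <- measure_timing(c(100, 200, 300), c(100, 200, 300), 10)
  expect_equal(exact$latency_mean_ms, 0)
  expect_equal(exact$jitter_ms, 0)

  tr <- measure_timing(c(99, 200, 301), c(100, 200, 300), 10)
  expect_equal(sort(tr$latencies_ms), c(-1, 0, 1))
  expect_equal(tr$jitter_ms, sd(c(-1, 0, 1)))
  expect_equal(tr$jitter_ms, 1)

  # events outside the acceptance window are not matched
  none <- measure_timing(c(500), c(100), 10)
  expect_equal(none$n_detected, 0)
  expect_true(is.na(none$latency_mean_ms))
})

test_that("greedy matching is one-to-one and prefers the nearest event", {
  # one trigger between two canonicals: only the nearer one is matched
  tr <- measure_timing(c(102), c(100, 110), 10)
  expect_equal(tr$latencies_ms, 2)
  expect_equal(tr$n_detected, 1)

  # two triggers, two canonicals: each canonical takes its own trigger
  tr2 <- measure_timing(c(101, 111), c(100, 110), 10)
  expect_equal(tr2$latencies_ms, c(1, 1))
})

test_that("accuracy reports match hand counts on a constructed trace", {
  y <- numeric(100)
  y[c(20, 21)] <- 0.9
  y[51] <- 0.8
  y[c(5, 30, 60, 70, 90)] <- 0.7
  out <- make_outputs(list(
    list(time_ms = 1:100, y = y, canonical = c(20, 50, 80))))
  rep <- accuracy_from_outputs(out, 0.5, cost_config(delta_t_ms = 2))
  expect_equal(rep$tp, 2)
  expect_equal(rep$fn, 1)
  expect_equal(rep$fp, 5)
  expect_equal(rep$n_events, 3)
  expect_equal(rep$tp_pct, 100 * 2 / 3)
  expect_equal(rep$n_negative_frames, 100 - 15)   # 3 windows of 5 frames
  expect_equal(rep$fp_pct, 100 * 5 / 85)
})

test_that("event-free corpora report NA TP rate and zero FP above max output", {
  out <- make_outputs(list(list(time_ms = 1:50, y = runif(50),
                                canonical = numeric(0))))
  rep <- accuracy_from_outputs(out, 2, cost_config())
  expect_true(is.na(rep$tp_pct))
  expect_equal(rep$fp_pct, 0)
})

test_that("evaluation refuses the corpus the model was trained on", {
  tm <- get_tiny_delta_fit()
  expect_error(evaluate_accuracy(tm$fit, tm$corpus), "held-out")
  # but the internal override allows training-set diagnostics
  rep <- evaluate_accuracy(tm$fit, tm$corpus, allow_training_corpus = TRUE)
  expect_s3_class(rep, "accuracy_report")
})

test_that("training-corpus accuracy is consistent with the optimized threshold", {
  tm <- get_tiny_delta_fit()
  fit <- tm$fit
  rep <- evaluate_accuracy(fit, tm$corpus, allow_training_corpus = TRUE)
  ct <- fit$threshold_counts[[1]]
  expect_equal(rep$tp, ct[["TP"]])
  expect_equal(rep$fn, ct[["FN"]])
  expect_equal(rep$fp, ct[["FP"]])
  # re-running the optimizer on recomputed outputs reproduces the stored
  # threshold and its minimum cost
  outputs <- corpus_outputs(fit, tm$corpus)
  th <- optimal_threshold(outputs, fit$cost)
  expect_equal(as.numeric(th), fit$thresholds[1])
  expect_equal(rep$fp + fit$cost$c_n * rep$fn, attr(th, "cost"))
})

test_that("frame-interval sweeps are reproducible and quantization-aware", {
  corpus <- generate_delta_corpus(n_songs = 30, seed = 6)
  cfg <- frame_config(interval_ms = 3, window_ms = 30)
  tc <- train_config(max_iter = 80, round_iter = 40, seed = 6)

  one <- sweep_frame_interval(corpus, 3, config = cfg, train = tc)
  expect_equal(nrow(one), 1)
  expect_equal(one$effective_interval_ms, 132 / 44.1)

  again <- sweep_frame_interval(corpus, 3, config = cfg, train = tc)
  expect_identical(one, again)

  both <- sweep_frame_interval(corpus, c(4, 1.5), config = cfg, train = tc)
  expect_equal(nrow(both), 2)
  # shorter frame interval does not worsen jitter (beyond sampling slack)
  expect_lte(both$jitter_ms[2], both$jitter_ms[1] + 0.2)
})
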