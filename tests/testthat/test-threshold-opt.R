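test_that("error counts behave at extreme thresholds", {
  out <- make_outputs(list(
    list(time_ms = 1:50, y = runif(50), canonical = c(10, 30)),
    list(time_ms = 1:50, y = runif(50), canonical = numeric(0))))
  cost <- cost_config(delta_t_ms = 3)

  hi <- count_errors(out, 2, cost)          # above every output
  expect_equal(unname(hi), c(0, 2, 0))

  lo <- count_errors(out, -1, cost)         # below every output
  expect_equal(lo[["TP"]], 2)
  expect_equal(lo[["FN"]], 0)
  # FP = all frames outside the two acceptance windows (7 frames each) in the
  # song clip, plus every frame of the event-free clip
  expect_equal(lo[["FP"]], (50 - 14) + 50)
  expect_equal(syldetect:::.n_negative_frames(out, 3), (50 - 14) + 50)
})

test_that("error counts match a hand-enumerated toy trace", {
  # 3 events; outputs exceed 0.5 near events 1 and 2 plus 5 stray frames
  y <- numeric(100)
  y[c(20, 21)] <- 0.9        # event at 20 ms -> TP
  y[c(51)] <- 0.8            # event at 50 ms (delta_t 2) -> TP
  y[c(5, 30, 60, 70, 90)] <- 0.7  # stray frames, far from events
  out <- make_outputs(list(
    list(time_ms = 1:100, y = y, canonical = c(20, 50, 80))))
  ce <- count_errors(out, 0.5, cost_config(delta_t_ms = 2))
  expect_equal(unname(ce), c(5, 1, 2))      # FP, FN, TP
})

test_that("overlapping acceptance windows assign one frame to at most one event", {
  # two events 4 ms apart with delta_t 5: windows overlap heavily
  y <- numeric(30)
  y[12] <- 0.9                              # single above-threshold frame
  out <- make_outputs(list(
    list(time_ms = 1:30, y = y, canonical = c(10, 14))))
  ce <- count_errors(out, 0.5, cost_config(delta_t_ms = 5))
  expect_equal(ce[["TP"]], 1)               # one frame cannot satisfy both
  expect_equal(ce[["FN"]], 1)
  expect_equal(ce[["FP"]], 0)
})

test_that("perfectly separated outputs reach zero cost", {
  y <- numeric(40); y[20] <- 0.95
  out <- make_outputs(list(list(time_ms = 1:40, y = y, canonical = 20)))
  th <- optimal_threshold(out, cost_config(delta_t_ms = 3))
  expect_equal(attr(th, "cost"), 0)
  expect_lt(as.numeric(th), 0.95)
  ce <- count_errors(out, th, cost_config(delta_t_ms = 3))
  expect_equal(unname(ce), c(0, 0, 1))
})

test_that("midpoint-grid optimum equals a dense grid scan", {
  set.seed(77)
  cost <- cost_config(delta_t_ms = 3)
  for (i in 1:25) {
    tr <- random_trace()
    out <- make_outputs(list(tr))
    th <- optimal_threshold(out, cost)

    # independent dense-grid oracle over 1e4 thresholds
    grid <- seq(min(tr$y) - 0.01, max(tr$y) + 0.01, length.out = 1e4)
    inside <- rep(FALSE, length(tr$time_ms))
    ev_max <- vapply(tr$canonical, function(e) {
      w <- abs(tr$time_ms - e) <= 3
      inside <<- inside | w
      max(c(tr$y[w], -Inf))
    }, numeric(1))
    neg <- tr$y[!inside]
    fp <- colSums(outer(neg, grid, ">"))
    fn <- colSums(outer(ev_max, grid, "<="))
    oracle_min <- min(fp + cost$c_n * fn)
    expect_identical(attr(th, "cost"), oracle_min)
  }
})

test_that("the chosen threshold is monotone non-increasing in the FN cost", {
  set.seed(88)
  for (i in 1:20) {
    out <- make_outputs(list(random_trace()))
    ths <- vapply(c(0.5, 1, 2, 4, 8), function(cn) {
      as.numeric(optimal_threshold(out, cost_config(c_n = cn, delta_t_ms = 3)))
    }, numeric(1))
    expect_true(all(diff(ths) <= 1e-12))
  }
})

test_that("FP is non-increasing and FN non-decreasing in the threshold", {
  set.seed(99)
  tr <- random_trace()
  out <- make_outputs(list(tr))
  cost <- cost_config(delta_t_ms = 3)
  ths <- sort(unique(tr$y))
  fps <- integer(0); fns <- integer(0)
  for (th in ths) {
    ce <- count_errors(out, th, cost)
    fps <- c(fps, ce[["FP"]]); fns <- c(fns, ce[["FN"]])
  }
  expect_true(all(diff(fps) <= 0))
  expect_true(all(diff(fns) >= 0))
})
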