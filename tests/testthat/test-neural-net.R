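test_that("forward pass matches hand-computed arithmetic", {
  p0 <- list(W0 = matrix(0, 2, 3), b0 = c(0, 0),
             W1 = matrix(0, 1, 2), b1 = 5)
  expect_equal(nn_forward(p0, c(1, 2, 3)), 5)      # all-zero weights -> b1

  p1 <- list(W0 = matrix(rnorm(6), 2, 3), b0 = c(0, 0),
             W1 = matrix(rnorm(2), 1, 2), b1 = -0.3)
  expect_equal(nn_forward(p1, c(0, 0, 0)), -0.3)   # tanh(0) = 0

  # 2x2 hand-set oracle, element by element
  p2 <- list(W0 = matrix(c(0.5, -1, 0.25, 2), 2, 2), b0 = c(0.1, -0.2),
             W1 = matrix(c(1, -3, 2, 0.5), 2, 2), b1 = c(0.05, -0.05))
  x <- c(0.3, -0.7)
  h1 <- tanh(0.5 * 0.3 + 0.25 * (-0.7) + 0.1)
  h2 <- tanh(-1 * 0.3 + 2 * (-0.7) - 0.2)
  expect_equal(nn_forward(p2, x),
               c(1 * h1 + 2 * h2 + 0.05, -3 * h1 + 0.5 * h2 - 0.05))

  # matrix input = column-wise application
  X <- matrix(rnorm(6), 2, 3)
  Y <- nn_forward(p2, X)
  expect_equal(Y[, 2], nn_forward(p2, X[, 2]))
  expect_error(nn_forward(p2, c(1, 2, 3)), "dimension")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(3)
  n_in <- 6; nh <- 3; n_out <- 2; n <- 10
  X <- matrix(rnorm(n_in * n), n_in, n)
  Y <- matrix(runif(n_out * n), n_out, n)
  params <- syldetect:::.init_params(n_in, nh, n_out)
  theta <- syldetect:::.pack_params(params)
  lg <- syldetect:::.nn_loss_grad(params, X, Y)
  g_ana <- syldetect:::.pack_params(lg$grad)
  f <- function(th) {
    p <- syldetect:::.unpack_params(th, n_in, nh, n_out)
    syldetect:::.nn_loss_grad(p, X, Y)$loss
  }
  h <- 1e-6
  g_num <- vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_ana - g_num)) / max(abs(g_num)), 1e-4)
})

test_that("the trainer solves a linearly separable toy problem", {
  set.seed(10)
  n_in <- 4
  pos <- matrix(rnorm(n_in * 30, mean = 2, sd = 0.3), n_in, 30)
  neg <- matrix(rnorm(n_in * 30, mean = -2, sd = 0.3), n_in, 30)
  X <- cbind(pos, neg)
  Y <- matrix(rep(c(1, 0), each = 30), 1)
  fit <- train_network(X, Y, train_config(max_iter = 200, round_iter = 40,
                                          seed = 2))
  out <- nn_forward(fit$params, X)
  expect_true(all(out[1, 1:30] >= 0.9))
  expect_true(all(out[1, 31:60] <= 0.1))
})

test_that("training is deterministic given the seed and tracks best validation", {
  set.seed(11)
  X <- matrix(rnorm(4 * 60), 4, 60)
  Y <- matrix(as.numeric(colSums(X) > 0), 1)
  Y[1, which(Y == 1)[1]] <- 1
  cfg <- train_config(max_iter = 120, round_iter = 20, seed = 9)
  f1 <- train_network(X, Y, cfg)
  f2 <- train_network(X, Y, cfg)
  expect_identical(f1$params, f2$params)
  # accepted-best validation MSE never increases across rounds
  expect_true(all(diff(f1$history$best_val) <= 0))
})

test_that("a syllable with no positive examples is refused by name", {
  X <- matrix(rnorm(4 * 20), 4, 20)
  Y <- rbind(c(1, numeric(19)), numeric(20))
  expect_error(train_network(X, Y, train_config()),
               "no positive training examples for syllable 2")
})

test_that("models round-trip bit-for-bit through the model file", {
  tm <- get_tiny_delta_fit()
  fit <- tm$fit
  p <- withr::local_tempfile(fileext = ".json")
  save_model(fit, p)
  back <- load_model(p)
  expect_identical(back$params, fit$params)
  expect_identical(back$norm$mu, fit$norm$mu)
  expect_identical(back$norm$sigma, fit$norm$sigma)
  expect_identical(back$thresholds, fit$thresholds)
  expect_identical(back$config$hop, fit$config$hop)
  x <- rnorm(ncol(fit$params$W0))
  expect_identical(nn_forward(back$params, x), nn_forward(fit$params, x))

  # truncated file errors rather than yielding garbage
  txt <- readChar(p, file.size(p))
  p2 <- withr::local_tempfile(fileext = ".json")
  writeChar(substr(txt, 1, nchar(txt) %/% 2), p2, eos = NULL)
  expect_error(load_model(p2), "corrupted|truncated")

  # rate mismatch is refused at prediction time
  expect_error(predict(fit, list(samples = rnorm(5000), rate = 48000)),
               "mismatch")
})
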