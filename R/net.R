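#' Training configuration for the detector network
#'
#' @param hidden_per_target Hidden units per target syllable; the hidden layer
#'   has `hidden_per_target * n_targets` units. Default 4 — a small hidden
#'   layer is a good compromise between accuracy and training speed for
#'   stereotyped song.
#' @param train_frac Fraction of training columns used for gradient steps;
#'   the remainder is the validation split for early stopping. Default 0.8.
#' @param max_iter Total quasi-Newton iteration budget. Default 400.
#' @param round_iter Iterations per optimization round; validation loss is
#'   checked between rounds. Default 40.
#' @param patience Rounds without validation improvement before stopping.
#'   Default 5.
#' @param seed Seed for weight initialization and the train/validation split.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(hidden_per_target = 4, train_frac = 0.8,
                         max_iter = 400, round_iter = 40, patience = 5,
                         seed = 1) {
  if (hidden_per_target < 1) stop("hidden_per_target must be at least 1")
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1")
  }
  structure(list(hidden_per_target = as.integer(hidden_per_target),
                 train_frac = train_frac, val_frac = 1 - train_frac,
                 max_iter = as.integer(max_iter),
                 round_iter = as.integer(round_iter),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Two-layer perceptron forward pass
#'
#' `y = W1 %*% tanh(W0 %*% x + b0) + b1`: a linear output layer over a small
#' tanh hidden layer. A pure function of its arguments.
#'
#' @param params List with matrices `W0` (`n_hidden x n_in`), `W1`
#'   (`n_out x n_hidden`) and bias vectors `b0`, `b1`.
#' @param x Feature-normalized input: vector of length `n_in` or matrix with
#'   one input per column.
#' @return Output vector of length `n_out`, or `n_out x n_cols` matrix.
#' @export
nn_forward <- function(params, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  if (nrow(x) != ncol(params$W0)) {
    stop("input dimension ", nrow(x), " does not match network input size ",
         ncol(params$W0))
  }
  H <- tanh(params$W0 %*% x + params$b0)
  Y <- params$W1 %*% H + params$b1
  if (vec) as.vector(Y) else Y
}

.init_params <- function(n_in, n_hidden, n_out) {
  a0 <- 1 / sqrt(n_in)
  a1 <- 1 / sqrt(n_hidden)
  list(W0 = matrix(stats::runif(n_hidden * n_in, -a0, a0), n_hidden, n_in),
       b0 = stats::runif(n_hidden, -a0, a0),
       W1 = matrix(stats::runif(n_out * n_hidden, -a1, a1), n_out, n_hidden),
       b1 = stats::runif(n_out, -a1, a1))
}

.pack_params <- function(p) {
  c(as.vector(p$W0), p$b0, as.vector(p$W1), p$b1)
}

.unpack_params <- function(theta, n_in, n_hidden, n_out) {
  i <- 0L
  take <- function(k) {
    v <- theta[(i + 1L):(i + k)]
    i <<- i + k
    v
  }
  list(W0 = matrix(take(n_hidden * n_in), n_hidden, n_in),
       b0 = take(n_hidden),
       W1 = matrix(take(n_out * n_hidden), n_out, n_hidden),
       b1 = take(n_out))
}

# Mean-squared-error loss and its analytic gradient.
# L = mean((W1 tanh(W0 X + b0) + b1 - Y)^2) over all outputs and columns.
.nn_loss_grad <- function(params, X, Y) {
  n <- ncol(X)
  n_out <- nrow(Y)
  H <- tanh(params$W0 %*% X + params$b0)
  E <- params$W1 %*% H + params$b1 - Y
  loss <- sum(E * E) / (n_out * n)
  dY <- E * (2 / (n_out * n))
  dW1 <- tcrossprod(dY, H)
  db1 <- rowSums(dY)
  dH <- crossprod(params$W1, dY)
  dZ <- dH * (1 - H * H)
  dW0 <- tcrossprod(dZ, X)
  db0 <- rowSums(dZ)
  list(loss = loss, grad = list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1))
}

.nn_mse <- function(params, X, Y) {
  E <- nn_forward(params, X) - Y
  sum(E * E) / length(E)
}

#' Train the detector network
#'
#' Minimizes mean squared error between the linear network outputs and the
#' Gaussian-smoothed targets by full-batch limited-memory quasi-Newton descent
#' (`stats::optim(method = "L-BFGS-B")` over the analytic gradients), run in
#' rounds with early stopping: after each round the MSE on a held-aside validation
#' split is evaluated and the best-validation parameters are retained. The
#' split is random by column but stratified so that positive-target columns
#' appear in both splits. Deterministic given `cfg$seed`.
#'
#' @param X Feature-normalized training matrix (features x columns).
#' @param Y Target matrix (`n_targets x columns`).
#' @param cfg A [train_config()].
#' @return List with `params` (best-validation network parameters), `history`
#'   (data frame of per-round train/validation MSE) and `val_mse`.
#' @export
train_network <- function(X, Y, cfg = train_config()) {
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == ncol(Y))
  n_t <- nrow(Y)
  for (k in seq_len(n_t)) {
    if (!any(Y[k, ] >= 0.999)) {
      stop("no positive training examples for syllable ", k)
    }
  }
  n_in <- nrow(X)
  n_hidden <- cfg$hidden_per_target * n_t
  .with_seed(cfg$seed, {
    pos <- which(apply(Y >= 0.5, 2, any))
    neg <- setdiff(seq_len(ncol(X)), pos)
    tr <- c(sample(pos, max(1L, floor(cfg$train_frac * length(pos)))),
            sample(neg, floor(cfg$train_frac * length(neg))))
    va <- setdiff(seq_len(ncol(X)), tr)
    if (length(va) == 0) stop("validation split is empty; reduce train_frac")
    Xt <- X[, tr, drop = FALSE]; Yt <- Y[, tr, drop = FALSE]
    Xv <- X[, va, drop = FALSE]; Yv <- Y[, va, drop = FALSE]

    params <- .init_params(n_in, n_hidden, n_t)
    theta <- .pack_params(params)

    # fn and gr share one forward/backward evaluation per point
    cache <- new.env(parent = emptyenv())
    evaluate <- function(th) {
      if (is.null(cache$theta) || !identical(th, cache$theta)) {
        p <- .unpack_params(th, n_in, n_hidden, n_t)
        lg <- .nn_loss_grad(p, Xt, Yt)
        cache$theta <- th
        cache$loss <- lg$loss
        cache$grad <- .pack_params(lg$grad)
      }
      invisible(NULL)
    }
    fn <- function(th) { evaluate(th); cache$loss }
    gr <- function(th) { evaluate(th); cache$grad }

    best <- list(theta = theta,
                 val = .nn_mse(.unpack_params(theta, n_in, n_hidden, n_t),
                               Xv, Yv))
    history <- list()
    iter_used <- 0L
    stale <- 0L
    round <- 0L
    while (iter_used < cfg$max_iter) {
      round <- round + 1L
      res <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = cfg$round_iter))
      theta <- res$par
      iter_used <- iter_used + cfg$round_iter
      p <- .unpack_params(theta, n_in, n_hidden, n_t)
      val <- .nn_mse(p, Xv, Yv)
      history[[round]] <- data.frame(round = round, train_mse = res$value,
                                     val_mse = val, best_val = min(best$val, val))
      if (val < best$val) {
        best$theta <- theta
        best$val <- val
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= cfg$patience) break
      if (res$convergence == 0) break  # optimizer converged within the round
    }
    list(params = .unpack_params(best$theta, n_in, n_hidden, n_t),
         history = do.call(rbind, history), val_mse = best$val,
         trainer = "stats::optim L-BFGS-B, full batch, analytic gradients")
  })
}
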