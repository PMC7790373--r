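#' Specify a feed-forward network
#'
#' One to three fully connected hidden layers with a smooth sigmoidal
#' activation and a single linear output neuron, trained by full-batch
#' gradient descent with momentum against a ridge-penalized mean squared
#' error.  The learning rate is self-tuned by a "bold driver" rule (grown
#' gently while the loss falls, halved when it rises) up to `lr_max`, so no
#' per-dataset rate tuning is needed; the output bias starts at the
#' training outcome mean, a natural initialization for count outcomes kept
#' on their raw scale.  There is no early stopping: every fit spends the
#' full iteration budget, so grid cells are compared under budget parity.
#'
#' The default weight decay (`decay = 0.3`, a quadratic penalty on the
#' weights, never the biases) is the standard ridge regularization of
#' MLP regression.  It keeps a heavily over-parameterized network close to
#' the constant-mean predictor when the outcomes carry no signal -- the
#' behaviour visible in published permuted-outcome CV grids, whose errors
#' track the outcome variance -- while leaving genuine structure
#' learnable.  Set `decay = 0` for pure MSE minimization.
#'
#' @param input_width number of input neurons (feature columns).
#' @param hidden integer vector of 1-3 hidden-layer widths; the grid
#'   experiments draw widths from \{6, 12, 24, 36, 48, 60\}.
#' @param activation `"logistic"` or `"tanh"`.
#' @param max_iterations full-batch weight updates (default 50000).
#' @param seed integer seed for weight initialization.
#' @param decay ridge penalty coefficient on the squared weights.
#' @param learning_rate initial learning rate.
#' @param momentum classical momentum coefficient.
#' @param lr_growth,lr_shrink,lr_max bold-driver multipliers and cap.
#' @return a `network_spec` list.
#' @export
network_spec <- function(input_width, hidden = c(12L, 12L),
                         activation = c("logistic", "tanh"),
                         max_iterations = 50000L, seed = 1L,
                         decay = 0.3, learning_rate = 1e-4, momentum = 0.9,
                         lr_growth = 1.05, lr_shrink = 0.5, lr_max = 0.03) {
  activation <- match.arg(activation)
  input_width <- as.integer(input_width)
  hidden <- as.integer(hidden)
  if (input_width < 1) stopf("input_width must be >= 1")
  if (length(hidden) < 1 || length(hidden) > 3 || any(hidden < 1)) {
    stopf("hidden must be 1-3 positive layer widths")
  }
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  if (decay < 0) stopf("decay must be >= 0")
  structure(list(input_width = input_width, hidden = hidden,
                 activation = activation,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), decay = decay,
                 learning_rate = learning_rate, momentum = momentum,
                 lr_growth = lr_growth, lr_shrink = lr_shrink,
                 lr_max = lr_max),
            class = "network_spec")
}

#' Number of free parameters in a dense network
#'
#' Sum over layers of `(fan_in + 1) * fan_out` (weights plus a bias per
#' neuron), plus `(last_hidden + 1)` for the single linear output.  An
#' empty layout is the linear model with `input_width + 1` parameters.
#' The count is strictly increasing in every width and in depth at fixed
#' widths.
#'
#' @param input_width input neurons.
#' @param hidden integer vector of hidden widths (possibly empty).
#' @return integer parameter count.
#' @examples
#' count_parameters(83, c(6, 6))   # 553
#' @export
count_parameters <- function(input_width, hidden = integer(0)) {
  widths <- c(as.integer(input_width), as.integer(hidden), 1L)
  sum((widths[-length(widths)] + 1L) * widths[-1])
}

act_fun <- function(name) {
  switch(name,
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(a) a * (1 - a)),
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         stopf("unknown activation '%s'", name))
}

# Glorot-uniform weights; the output bias is set to mean(y) by the trainer
init_layers <- function(spec) {
  widths <- c(spec$input_width, spec$hidden, 1L)
  with_seed(spec$seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      fan_in <- widths[l]; fan_out <- widths[l + 1L]
      r <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out),
           b = stats::runif(fan_out, -r, r))
    })
  })
}

forward_pass <- function(layers, X, act) {
  n_layers <- length(layers)
  acts <- vector("list", n_layers + 1L)
  acts[[1]] <- X
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      rep(layers[[l]]$b, each = nrow(acts[[l]]))
    acts[[l + 1L]] <- if (l < n_layers) act$f(z) else z  # linear output
  }
  acts
}

#' Train a network by full-batch gradient descent
#'
#' Runs exactly `spec$max_iterations` full-batch updates of momentum
#' gradient descent on the ridge-penalized training MSE, with the
#' bold-driver learning-rate schedule described in [network_spec()].
#' Deterministic given `(X, y, spec)`: the only randomness is the seeded
#' weight initialization.  Inputs are used as given; standardize them
#' first (see [standardize()]), as [cv_run()] does per fold.
#'
#' @param X numeric training matrix, rows = days; no missing values.
#' @param y numeric outcome vector (daily deaths, raw count scale).
#' @param spec a [network_spec()] with `input_width == ncol(X)`.
#' @param scaling optional scaling record to store alongside the weights.
#' @return a `lagcv_network`: `layers` (weights/biases), `loss_trace`
#'   (unpenalized training MSE per iteration), `iterations`, `spec`,
#'   `scaling`.
#' @export
train_network <- function(X, y, spec, scaling = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2) stopf("need at least 2 training rows")
  if (nrow(X) != length(y)) stopf("X and y disagree on the number of rows")
  if (anyNA(X) || any(!is.finite(X)) || any(!is.finite(y))) {
    stopf("training data must be finite with no missing values")
  }
  if (ncol(X) != spec$input_width) {
    stopf("X has %d columns but the spec expects %d", ncol(X), spec$input_width)
  }
  act <- act_fun(spec$activation)
  layers <- init_layers(spec)
  n_layers <- length(layers)
  layers[[n_layers]]$b <- mean(y)
  n <- nrow(X)

  vel <- lapply(layers, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
  })
  lr <- spec$learning_rate
  prev_loss <- Inf
  loss_trace <- numeric(spec$max_iterations)

  for (it in seq_len(spec$max_iterations)) {
    acts <- forward_pass(layers, X, act)
    resid <- acts[[n_layers + 1L]] - y
    loss_trace[it] <- mean(resid^2)
    penalty <- spec$decay *
      sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
    loss <- loss_trace[it] + penalty
    lr <- if (loss > prev_loss * (1 + 1e-4)) lr * spec$lr_shrink else
      min(lr * spec$lr_growth, spec$lr_max)
    prev_loss <- loss

    delta <- (2 / n) * resid                       # dL/d(output z)
    for (l in rev(seq_len(n_layers))) {
      gW <- crossprod(acts[[l]], delta) + 2 * spec$decay * layers[[l]]$W
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(layers[[l]]$W)) * act$df(acts[[l]])
      }
      vel[[l]]$W <- spec$momentum * vel[[l]]$W - lr * gW
      vel[[l]]$b <- spec$momentum * vel[[l]]$b - lr * gb
      layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
      layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
    }
  }
  structure(list(layers = layers, loss_trace = loss_trace,
                 iterations = spec$max_iterations, spec = spec,
                 scaling = scaling),
            class = "lagcv_network")
}

#' Predict daily deaths from a fitted network
#'
#' If the network stores a scaling record it is applied to `newdata`
#' first; otherwise rows must already be on the training scale.
#'
#' @param object a `lagcv_network` from [train_network()].
#' @param newdata numeric matrix with `spec$input_width` columns.
#' @param ... unused.
#' @return numeric vector, one prediction per row.
#' @export
predict.lagcv_network <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$spec$input_width) {
    stopf("newdata has %d columns but the network expects %d",
          ncol(X), object$spec$input_width)
  }
  if (!is.null(object$scaling)) X <- apply_scaling(object$scaling, X)
  act <- act_fun(object$spec$activation)
  drop(forward_pass(object$layers, X, act)[[length(object$layers) + 1L]])
}

#' @export
print.lagcv_network <- function(x, ...) {
  cat(sprintf("<lagcv_network> %d-%s-1, %d iterations, final MSE %.4g\n",
              x$spec$input_width, paste(x$spec$hidden, collapse = "-"),
              x$iterations, x$loss_trace[x$iterations]))
  invisible(x)
}

#' Mean squared error
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return mean of squared differences, in (deaths/day)^2 for mortality.
#' @examples
#' mse(c(0, 0), c(3, 4))  # 12.5
#' @export
mse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stopf("length mismatch")
  if (length(predicted) == 0) stopf("empty vectors")
  mean((predicted - observed)^2)
}

#' Save or load a fitted network as a single portable file
#'
#' Layer sizes, flat weight arrays, the spec and any scaling record,
#' serialized with base R.
#'
#' @param net a `lagcv_network`.
#' @param path file path.
#' @return `read_network()` returns the network; `write_network()` returns
#'   `path` invisibly.
#' @export
write_network <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) readRDS(path)
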