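# From-scratch single-hidden-layer perceptron trained by full-batch gradient
# descent on the sum-form squared-error objective
#
#   E = 1/2 * sum_p sum_k (d_k^p - o_k^p)^2
#
# with units  y_j = f(sum_i w_ji x_i - theta_j)  (biases subtracted, trained
# as weights on a constant -1 input). Backpropagation deltas:
#   D'_k = (d_k - o_k) f'(v'_k),   D_j = (sum_k D'_k w'_kj) f'(v_j).
# The summed batch step is divided by the number of patterns by default
# (batch_scale = "mean"); the raw summed step is available as "sum" but at
# practical learning rates it saturates the sigmoids on realistically sized
# training sets (see the methods vignette).

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, the network's default transfer function; maps onto
#' (0, 1) and is numerically stable across the full double range.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(log(3)) # 0.75
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Hidden-layer sizing heuristic
#'
#' `round(((n_in + n_out) / 3) * 2)`, rounding half away from zero. A common
#' rule of thumb for the single hidden layer; callers may always override the
#' result explicitly.
#'
#' @param n_in,n_out Positive integer layer sizes.
#' @return Integer number of hidden neurons.
#' @examples
#' size_hidden(15, 5) # 13
#' size_hidden(3, 3)  # 4
#' @export
size_hidden <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  as.integer(floor(((n_in + n_out) / 3) * 2 + 0.5))
}

# transfer function table: f on hidden layer, g on output layer (tanh output
# is affinely rescaled onto (0, 1) so one-hot targets stay representable);
# derivatives are expressed in terms of the activation
transfer_funs <- function(transfer) {
  switch(transfer,
    sigmoid = list(
      f = sigmoid, fprime = function(a) a * (1 - a),
      g = sigmoid, gprime = function(a) a * (1 - a)
    ),
    tanh = list(
      f = tanh, fprime = function(a) 1 - a^2,
      g = function(x) (tanh(x) + 1) / 2, gprime = function(a) 2 * a * (1 - a)
    ),
    stop_skel(paste("unknown transfer function:", transfer), "bad_config")
  )
}

as_one_hot <- function(y, levels = NULL) {
  if (is.matrix(y)) {
    stopifnot(all(y %in% c(0, 1)), all(rowSums(y) == 1))
    if (is.null(colnames(y))) colnames(y) <- paste0("class", seq_len(ncol(y)))
    return(y)
  }
  f <- if (is.factor(y)) y else factor(y, levels = levels %||% sort(unique(as.character(y))))
  if (anyNA(f)) stop_skel("labels outside the declared levels", "bad_labels")
  m <- diag(nlevels(f))[as.integer(f), , drop = FALSE]
  colnames(m) <- levels(f)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a multilayer perceptron
#'
#' Trains a single-hidden-layer perceptron on feature vectors in \[0, 1\] by
#' full-batch backpropagation gradient descent, stopping when the sum-form
#' squared error drops to `max_error` or after `max_epochs` epochs. Training
#' is deterministic given `seed` (which controls the symmetric uniform weight
#' initialization).
#'
#' @param x Numeric matrix of training patterns (rows) with values in \[0, 1\].
#' @param y Class labels (factor/character) or a one-hot target matrix.
#' @param n_hidden Number of hidden neurons; defaults to [size_hidden()].
#' @param transfer `"sigmoid"` (default) or `"tanh"`. With `tanh`, hidden units
#'   use tanh and the output layer uses tanh rescaled onto (0, 1).
#' @param learning_rate Gradient step size, default 0.3.
#' @param max_error Stop threshold on the sum-form error E, default 0.01.
#' @param max_epochs Epoch cap, default 20000.
#' @param seed Integer seed for weight initialization.
#' @param init_scale Weights start uniform in `[-init_scale, init_scale]`.
#' @param batch_scale `"mean"` (default) divides the summed batch gradient by
#'   the number of patterns; `"sum"` applies the raw summed step.
#' @param levels Optional explicit class levels when `y` is character.
#' @return An object of class `mlp` with weights, the training trace (per-epoch
#'   error), `epochs`, `converged`, and the label map. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(runif(40, 0, .4), 20), matrix(runif(40, .6, 1), 20))
#' y <- rep(c("low", "high"), each = 20)
#' fit <- mlp(x, y, n_hidden = 3, max_epochs = 2000, seed = 1)
#' table(predict(fit, x), y)
#' @export
mlp <- function(x, y, n_hidden = NULL,
                transfer = c("sigmoid", "tanh"),
                learning_rate = 0.3, max_error = 0.01, max_epochs = 20000L,
                seed = 1L, init_scale = 0.5,
                batch_scale = c("mean", "sum"), levels = NULL) {
  transfer <- match.arg(transfer)
  batch_scale <- match.arg(batch_scale)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop_skel("non-finite training inputs", "bad_inputs")
  if (any(x < 0 | x > 1)) stop_skel("training inputs must lie in [0, 1]", "bad_inputs")
  d <- as_one_hot(y, levels)
  if (nrow(d) != nrow(x)) stop_skel("x and y disagree on the number of patterns", "shape")
  if (nrow(x) == 0L) stop_skel("empty training set", "bad_inputs")
  stopifnot(learning_rate >= 0, max_error >= 0, max_epochs >= 1, init_scale > 0)

  n_in <- ncol(x); n_out <- ncol(d)
  n_hidden <- as.integer(n_hidden %||% size_hidden(n_in, n_out))
  stopifnot(n_hidden >= 1)

  net <- mlp_init(n_in, n_hidden, n_out, transfer, seed, init_scale)
  net$config <- list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                     transfer = transfer, learning_rate = learning_rate,
                     max_error = max_error, max_epochs = as.integer(max_epochs),
                     seed = as.integer(seed), init_scale = init_scale,
                     batch_scale = batch_scale)
  net$levels <- colnames(d)
  net <- train_mlp(net, x, d)
  net$x <- x
  net$d <- d
  net$call <- match.call()
  net
}

mlp_init <- function(n_in, n_hidden, n_out, transfer, seed, init_scale) {
  set.seed(as.integer(seed))
  structure(list(
    W1 = matrix(stats::runif(n_hidden * n_in, -init_scale, init_scale), n_hidden, n_in),
    b1 = stats::runif(n_hidden, -init_scale, init_scale),
    W2 = matrix(stats::runif(n_out * n_hidden, -init_scale, init_scale), n_out, n_hidden),
    b2 = stats::runif(n_out, -init_scale, init_scale),
    transfer = transfer
  ), class = "mlp")
}

#' Forward propagation
#'
#' @param object A fitted or initialized `mlp`.
#' @param x Feature matrix (or single vector) with `n_in` columns.
#' @return List with `hidden` (P x H activations) and `output` (P x K).
#' @export
forward_mlp <- function(object, x) {
  stopifnot(inherits(object, "mlp"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(object$W1))
    stop_skel(sprintf("input has %d features, network expects %d", ncol(x), ncol(object$W1)),
              "shape")
  tf <- transfer_funs(object$transfer)
  a1 <- tf$f(x %*% t(object$W1) - rep(object$b1, each = nrow(x)))
  a2 <- tf$g(a1 %*% t(object$W2) - rep(object$b2, each = nrow(x)))
  colnames(a2) <- object$levels
  list(hidden = a1, output = a2)
}

#' Sum-form squared error of a network on a pattern set
#'
#' `E = 1/2 sum_p sum_k (d - o)^2`, the objective the network is trained on.
#' Note the sum runs over patterns without averaging; `per_pattern = TRUE`
#' divides by the number of patterns for reporting.
#'
#' @param object A `mlp`.
#' @param x Feature matrix.
#' @param y Labels or one-hot target matrix aligned with `x`.
#' @param per_pattern Divide by the number of patterns (default `FALSE`).
#' @return Non-negative scalar.
#' @export
mlp_mse <- function(object, x, y, per_pattern = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) == 0L) stop_skel("empty pattern set", "bad_inputs")
  d <- as_one_hot(y, object$levels)
  o <- forward_mlp(object, x)$output
  e <- 0.5 * sum((d - o)^2)
  if (per_pattern) e / nrow(x) else e
}

# Analytic gradient of the sum-form E with respect to every weight and bias.
# Returned as dE/dw (not the update step); training applies
# w <- w - learning_rate * scale * dE/dw.
mlp_gradients <- function(object, x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  tf <- transfer_funs(object$transfer)
  P <- nrow(x)
  a1 <- tf$f(x %*% t(object$W1) - rep(object$b1, each = P))
  a2 <- tf$g(a1 %*% t(object$W2) - rep(object$b2, each = P))
  d2 <- (d - a2) * tf$gprime(a2)           # P x K
  d1 <- (d2 %*% object$W2) * tf$fprime(a1) # P x H
  list(
    W1 = -t(d1) %*% x,
    b1 = colSums(d1),    # bias input is the constant -1
    W2 = -t(d2) %*% a1,
    b2 = colSums(d2)
  )
}

# Full-batch gradient-descent training loop. Returns the network with the
# per-epoch error trace, final epoch count and convergence flag attached.
train_mlp <- function(net, x, d) {
  cfg <- net$config
  scale <- if (cfg$batch_scale == "mean") 1 / nrow(x) else 1
  eps <- cfg$learning_rate
  trace <- numeric(cfg$max_epochs)
  tf <- transfer_funs(net$transfer)
  W1 <- net$W1; b1 <- net$b1; W2 <- net$W2; b2 <- net$b2
  P <- nrow(x)
  converged <- FALSE
  epoch <- 0L
  e <- NA_real_
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    a1 <- tf$f(x %*% t(W1) - rep(b1, each = P))
    a2 <- tf$g(a1 %*% t(W2) - rep(b2, each = P))
    r <- d - a2
    e <- 0.5 * sum(r * r)
    trace[epoch] <- e
    if (!is.finite(e)) stop_skel("training diverged (non-finite error)", "training_diverged")
    if (e <= cfg$max_error) { converged <- TRUE; break }
    d2 <- r * tf$gprime(a2)
    d1 <- (d2 %*% W2) * tf$fprime(a1)
    step <- eps * scale
    W2 <- W2 + step * t(d2) %*% a1
    b2 <- b2 - step * colSums(d2)
    W1 <- W1 + step * t(d1) %*% x
    b1 <- b1 - step * colSums(d1)
  }
  net$W1 <- unname(W1); net$b1 <- unname(b1)
  net$W2 <- unname(W2); net$b2 <- unname(b2)
  net$trace <- trace[seq_len(epoch)]
  net$epochs <- epoch
  net$final_error <- e
  net$converged <- converged
  net
}

#' Decode network outputs into a class label
#'
#' The winning class is the arg-max output, accepted only when its activation
#' reaches `threshold` and exceeds the runner-up by at least `margin`;
#' otherwise `"none"`. Exact ties with `margin = 0` go to the lowest output
#' index.
#'
#' @param outputs Numeric vector or P x K matrix of network outputs.
#' @param labels Class names, one per output (defaults to names/colnames).
#' @param threshold Minimum winning activation, default 0.5.
#' @param margin Minimum lead over the runner-up, default 0.05.
#' @return Character vector of labels (or `"none"`).
#' @export
predict_label <- function(outputs, labels = NULL, threshold = 0.5, margin = 0.05) {
  if (is.null(dim(outputs))) outputs <- matrix(outputs, nrow = 1L,
                                               dimnames = list(NULL, names(outputs)))
  labels <- labels %||% colnames(outputs) %||% paste0("class", seq_len(ncol(outputs)))
  idx <- seq_len(nrow(outputs))
  best <- max.col(outputs, ties.method = "first")
  top <- outputs[cbind(idx, best)]
  if (ncol(outputs) > 1L) {
    rest <- outputs
    rest[cbind(idx, best)] <- -Inf
    second <- rest[cbind(idx, max.col(rest, ties.method = "first"))]
  } else second <- rep(-Inf, nrow(outputs))
  out <- labels[best]
  out[top < threshold | (top - second) < margin] <- "none"
  out
}

#' @export
print.mlp <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Multilayer perceptron %d-%d-%d (%s)\n",
              cfg$n_in, cfg$n_hidden, cfg$n_out, cfg$transfer))
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  trained %d epochs, final error %.4g (%sconverged at max_error %.3g)\n",
              x$epochs, x$final_error, if (x$converged) "" else "not ", cfg$max_error))
  invisible(x)
}

#' @export
summary.mlp <- function(object, ...) {
  pred <- predict(object, object$x, type = "class", threshold = 0, margin = 0)
  truth <- object$levels[max.col(object$d)]
  structure(list(net = object,
                 train_accuracy = mean(pred == truth),
                 class_table = table(truth = truth, predicted = pred),
                 per_pattern_error = object$final_error / nrow(object$x)),
            class = "summary.mlp")
}

#' @export
print.summary.mlp <- function(x, ...) {
  print(x$net)
  cat(sprintf("  training accuracy %.1f%%, per-pattern error %.4g\n",
              100 * x$train_accuracy, x$per_pattern_error))
  print(x$class_table)
  invisible(x)
}

#' @export
coef.mlp <- function(object, ...) {
  list(input_hidden = object$W1, hidden_bias = object$b1,
       hidden_output = object$W2, output_bias = object$b2)
}

#' Predict from a fitted perceptron
#'
#' @param object A fitted `mlp`.
#' @param newdata Feature matrix or vector.
#' @param type `"class"` (decoded labels, possibly `"none"`) or `"prob"` (raw
#'   output activations).
#' @param threshold,margin Decoding rule, see [predict_label()].
#' @param ... Unused.
#' @return Character vector of labels, or output matrix.
#' @export
predict.mlp <- function(object, newdata, type = c("class", "prob"),
                        threshold = 0.5, margin = 0.05, ...) {
  type <- match.arg(type)
  o <- forward_mlp(object, newdata)$output
  if (type == "prob") return(o)
  predict_label(o, object$levels, threshold, margin)
}

#' @export
fitted.mlp <- function(object, ...) forward_mlp(object, object$x)$output

#' @export
residuals.mlp <- function(object, ...) object$d - fitted(object)

#' @export
plot.mlp <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l", log = "y",
                 xlab = "epoch", ylab = "sum-form error E", ...)
  graphics::abline(h = x$config$max_error, lty = 2)
  invisible(x)
}
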