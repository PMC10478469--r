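#' Configuration of the backpropagation network
#'
#' The three-layer architecture and training settings used for yield
#' prediction: 3 inputs (the stage's nutrient concentrations), 10 tanh
#' hidden units, 1 linear output, trained by full-batch steepest descent
#' for 200 iterations at learning rate 0.01.
#'
#' @param n_input,n_hidden,n_output Layer sizes.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Number of full-batch iterations.
#' @param init_range Uniform initialisation range for weights and
#'   thresholds (also the metaheuristic search bounds).
#' @param seed Seed for weight initialisation.
#' @return An object of class `bp_config`.
#' @export
bp_config <- function(n_input = 3, n_hidden = 10, n_output = 1,
                      learning_rate = 0.01, epochs = 200,
                      init_range = c(-1, 1), seed = 1) {
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1,
            learning_rate >= 0, epochs >= 1, init_range[1] < init_range[2])
  structure(
    list(n_input = n_input, n_hidden = n_hidden, n_output = n_output,
         learning_rate = learning_rate, epochs = epochs,
         init_range = init_range, seed = as.integer(seed)),
    class = "bp_config"
  )
}

n_weights <- function(config) {
  config$n_input * config$n_hidden + config$n_hidden +
    config$n_hidden * config$n_output + config$n_output
}

#' Initialise a backpropagation network
#'
#' Weights and thresholds drawn uniformly from `init_range` under the
#' config's seed; the same uniform box is the metaheuristics' search
#' space, so a plain network and an optimizer-initialised network start
#' from comparable regions.
#'
#' @param config A [bp_config()].
#' @param scalers An `npk_scalers` from [fit_scalers()].
#' @return An untrained network of class `npk_bp`.
#' @export
bp_init <- function(config, scalers) {
  set.seed(config$seed)
  v <- runif(n_weights(config), config$init_range[1], config$init_range[2])
  bp_decode(v, config, scalers)
}

#' Flat weight-vector codec
#'
#' Encodes a network's weights and thresholds as one flat numeric vector —
#' the metaheuristic search space — in fixed layout order: input-to-hidden
#' weights row-major (by input), hidden thresholds, hidden-to-output
#' weights row-major, output threshold. Length 51 for the default 3-10-1
#' architecture. `bp_decode()` is its exact inverse.
#'
#' @param net An `npk_bp` network.
#' @return `bp_encode()`: a numeric vector; `bp_decode()`: an `npk_bp`.
#' @export
#' @examples
#' sc <- fit_scalers(matrix(runif(30), 10), seq(5000, 7000, length = 10))
#' net <- bp_init(bp_config(), sc)
#' length(bp_encode(net))
bp_encode <- function(net) {
  c(as.vector(t(net$W1)), net$b1, as.vector(t(net$W2)), net$b2)
}

#' @rdname bp_encode
#' @param vector Numeric vector of length `n_input * n_hidden + n_hidden +
#'   n_hidden * n_output + n_output`.
#' @param config A [bp_config()].
#' @param scalers An `npk_scalers`.
#' @export
bp_decode <- function(vector, config, scalers) {
  expected <- n_weights(config)
  if (length(vector) != expected) {
    abort(paste0("Weight vector has length ", length(vector),
                 ", expected ", expected, "."))
  }
  ni <- config$n_input; nh <- config$n_hidden; no <- config$n_output
  i <- 0
  W1 <- matrix(vector[i + seq_len(ni * nh)], nrow = ni, byrow = TRUE)
  i <- i + ni * nh
  b1 <- vector[i + seq_len(nh)]
  i <- i + nh
  W2 <- matrix(vector[i + seq_len(nh * no)], nrow = nh, byrow = TRUE)
  i <- i + nh * no
  b2 <- vector[i + seq_len(no)]
  structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
         config = config, scalers = scalers,
         trained = FALSE, loss_history = numeric(0)),
    class = "npk_bp"
  )
}

# forward pass in scaled space; Xs is n x n_input, already scaled
forward_scaled <- function(net, Xs) {
  H <- tanh(sweep(Xs %*% net$W1, 2, net$b1, "+"))
  list(H = H, yhat = as.vector(H %*% net$W2 + net$b2))
}

#' Forward pass of the network
#'
#' Evaluates `W2' tanh(W1' x + b1) + b2` on min-max-scaled inputs and
#' inverse-scales the output to t/ha. Deterministic and stateless.
#'
#' @param net An `npk_bp` network.
#' @param X Inputs on the original mg/L scale (n x n_input).
#' @return Predicted yields in t/ha.
#' @export
bp_forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$config$n_input) {
    abort(paste0("Input has ", ncol(X), " columns, expected ",
                 net$config$n_input, "."))
  }
  unscale_y(net$scalers, forward_scaled(net, scale_x(net$scalers, X))$yhat)
}

#' @export
predict.npk_bp <- function(object, newdata, ...) {
  bp_forward(object, newdata)
}

#' Training loss of a network
#'
#' Mean squared error in scaled space — the objective steepest descent
#' minimises during training.
#'
#' @param net An `npk_bp` network.
#' @param X Inputs (mg/L).
#' @param y Yields (kg/ha).
#' @return Scalar MSE in scaled space.
#' @export
bp_loss <- function(net, X, y) {
  Xs <- scale_x(net$scalers, X)
  ys <- scale_y(net$scalers, y)
  mean((forward_scaled(net, Xs)$yhat - ys)^2)
}

#' Analytic gradient of the training loss
#'
#' Backpropagated gradient of the scaled-space MSE with respect to the
#' flat weight vector, in [bp_encode()] layout. Exposed so the gradient can
#' be verified against finite differences.
#'
#' @inheritParams bp_loss
#' @return Numeric vector of the same length as [bp_encode()].
#' @export
bp_gradient <- function(net, X, y) {
  Xs <- scale_x(net$scalers, X)
  ys <- scale_y(net$scalers, y)
  n <- nrow(Xs)
  fw <- forward_scaled(net, Xs)
  e <- fw$yhat - ys               # n
  d_out <- 2 * e / n              # dL/dyhat
  gW2 <- crossprod(fw$H, d_out)   # nh x 1
  gb2 <- sum(d_out)
  dH <- (d_out %*% t(net$W2)) * (1 - fw$H^2) # n x nh
  gW1 <- crossprod(Xs, dH)        # ni x nh
  gb1 <- colSums(dH)
  c(as.vector(t(gW1)), gb1, as.vector(t(gW2)), gb2)
}

#' Train the network by steepest descent
#'
#' Full-batch gradient descent on the scaled-space mean squared error for
#' exactly `epochs` iterations — no momentum, no early stopping. The loss
#' history records the objective after each update; training aborts with
#' an error naming the epoch if the loss becomes non-finite.
#'
#' @param net An `npk_bp` network (e.g. from [bp_init()] or decoded from a
#'   metaheuristic's best weight vector).
#' @param X Training inputs (mg/L), at least 2 rows.
#' @param y Training yields (kg/ha).
#' @param config Training settings; defaults to the network's own config.
#' @return The trained `npk_bp`, with `$loss_history` (length `epochs`),
#'   `$initial_loss` and `$trained = TRUE`.
#' @export
bp_train <- function(net, X, y, config = net$config) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("Need at least 2 training samples.")
  lr <- config$learning_rate
  v <- bp_encode(net)
  history <- numeric(config$epochs)
  net$initial_loss <- bp_loss(net, X, y)
  for (epoch in seq_len(config$epochs)) {
    g <- bp_gradient(net, X, y)
    v <- v - lr * g
    net[c("W1", "b1", "W2", "b2")] <-
      bp_decode(v, net$config, net$scalers)[c("W1", "b1", "W2", "b2")]
    history[epoch] <- bp_loss(net, X, y)
    if (!is.finite(history[epoch])) {
      abort(paste0("Training diverged (non-finite loss) at epoch ",
                   epoch, "."))
    }
  }
  net$loss_history <- history
  net$trained <- TRUE
  net
}

#' @export
print.npk_bp <- function(x, ...) {
  cfg <- x$config
  cat("<npk_bp> ", cfg$n_input, "-", cfg$n_hidden, "-", cfg$n_output,
      " network (", if (x$trained) "trained" else "untrained", ")\n",
      sep = "")
  if (x$trained) {
    cat("  epochs:", cfg$epochs, " lr:", cfg$learning_rate,
        " final loss:", signif(utils::tail(x$loss_history, 1), 4), "\n")
  }
  invisible(x)
}

#' @export
tidy.npk_bp <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::expand_grid(from = seq_len(x$config$n_input),
                       to = seq_len(x$config$n_hidden)) |>
      dplyr::mutate(term = "input_hidden",
                    value = as.vector(t(x$W1))),
    tibble(term = "hidden_threshold", from = NA_integer_,
           to = seq_len(x$config$n_hidden), value = x$b1),
    tidyr::expand_grid(from = seq_len(x$config$n_hidden),
                       to = seq_len(x$config$n_output)) |>
      dplyr::mutate(term = "hidden_output",
                    value = as.vector(t(x$W2))),
    tibble(term = "output_threshold", from = NA_integer_,
           to = seq_len(x$config$n_output), value = x$b2)
  ) |>
    dplyr::select("term", "from", "to", "value")
}

#' @export
glance.npk_bp <- function(x, ...) {
  tibble(
    n_input = x$config$n_input, n_hidden = x$config$n_hidden,
    n_output = x$config$n_output,
    learning_rate = x$config$learning_rate, epochs = x$config$epochs,
    trained = x$trained,
    initial_loss = x$initial_loss %||% NA_real_,
    final_loss = if (length(x$loss_history)) {
      utils::tail(x$loss_history, 1)
    } else {
      NA_real_
    }
  )
}

#' Persist a fitted network as JSON
#'
#' Stores config, scalers and the flat weight vector; a written-then-read
#' network predicts identically.
#'
#' @param net An `npk_bp`.
#' @param path File path.
#' @return `write_bp_model()` returns `net` invisibly; `read_bp_model()`
#'   returns the network.
#' @export
write_bp_model <- function(net, path) {
  payload <- list(
    config = unclass(net$config),
    scalers = unclass(net$scalers),
    weights = bp_encode(net),
    trained = net$trained,
    loss_history = net$loss_history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(net)
}

#' @rdname write_bp_model
#' @export
read_bp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(bp_config, p$config[
    c("n_input", "n_hidden", "n_output", "learning_rate", "epochs",
      "init_range", "seed")])
  scalers <- structure(p$scalers, class = "npk_scalers")
  scalers$x_lo <- unlist(scalers$x_lo)
  scalers$x_hi <- unlist(scalers$x_hi)
  net <- bp_decode(p$weights, config, scalers)
  net$trained <- isTRUE(p$trained)
  net$loss_history <- p$loss_history %||% numeric(0)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
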