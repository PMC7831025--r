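#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, the activation used on every layer of the
#' autoencoder.
#'
#' @param x Numeric.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Autoencoder architecture specification
#'
#' A symmetric feed-forward autoencoder: the encoder maps
#' `input_dim -> hidden[1] -> ... -> bottleneck`, the decoder mirrors it back
#' to `input_dim`. Every layer uses the sigmoid activation; the final
#' (output) layer can optionally be linear.
#'
#' @param input_dim Input dimension (default 200, the reduced window length).
#' @param hidden Encoder hidden-layer widths (default `c(100, 50)`).
#' @param bottleneck Latent dimension (default 2).
#' @param output_activation `"sigmoid"` (inputs live in \[0,1\]) or
#'   `"linear"`.
#' @return An `AutoencoderSpec`.
#' @export
autoencoder_spec <- function(input_dim = 200, hidden = c(100, 50),
                             bottleneck = 2,
                             output_activation = c("sigmoid", "linear")) {
  output_activation <- match.arg(output_activation)
  widths <- c(input_dim, hidden, bottleneck, rev(hidden), input_dim)
  if (any(widths <= 0)) stop_cp("all layer widths must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 bottleneck = as.integer(bottleneck),
                 widths = as.integer(widths),
                 bottleneck_layer = length(hidden) + 1L,
                 output_activation = output_activation),
            class = "AutoencoderSpec")
}

#' Training hyperparameters for the autoencoder
#'
#' Adam stochastic gradient descent with Glorot-uniform initialization; all
#' randomness (initialization, batch shuffling) is governed by `seed`.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size.
#' @param seed Integer seed.
#' @param early_stop Optional list `list(patience =, min_delta =)`: stop when
#'   the full-data reconstruction error has not improved by `min_delta` for
#'   `patience` consecutive epochs.
#' @return A `TrainHyperparams`.
#' @export
train_hyperparams <- function(epochs = 200, batch_size = 64,
                              learning_rate = 1e-3, seed = 1,
                              early_stop = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_name = "adam",
                 seed = as.integer(seed),
                 early_stop = early_stop),
            class = "TrainHyperparams")
}

# Glorot-uniform parameter initialization for the layer widths.
ae_init_params <- function(widths) {
  n_layers <- length(widths) - 1L
  W <- vector("list", n_layers); b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lim <- sqrt(6 / (widths[l] + widths[l + 1]))
    W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1], -lim, lim),
                     widths[l], widths[l + 1])
    b[[l]] <- rep(0, widths[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass; returns the list of layer activations (A[[1]] = input).
ae_forward <- function(params, X, output_activation) {
  n_layers <- length(params$W)
  A <- vector("list", n_layers + 1L)
  A[[1]] <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    A[[l + 1]] <- if (l == n_layers && output_activation == "linear") Z
                  else sigmoid(Z)
  }
  A
}

# Mean squared reconstruction error J = (1/N) sum_i ||x_i' - x_i||^2.
ae_loss <- function(params, X, output_activation) {
  A <- ae_forward(params, X, output_activation)
  mean(rowSums((A[[length(A)]] - X)^2))
}

# Backpropagation of J; returns gradients shaped like params.
ae_grad <- function(params, X, output_activation) {
  n_layers <- length(params$W)
  A <- ae_forward(params, X, output_activation)
  N <- nrow(X)
  dW <- vector("list", n_layers); db <- vector("list", n_layers)
  dA <- 2 * (A[[n_layers + 1L]] - X) / N
  for (l in seq(n_layers, 1)) {
    out <- A[[l + 1L]]
    dZ <- if (l == n_layers && output_activation == "linear") dA
          else dA * out * (1 - out)
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1) dA <- dZ %*% t(params$W[[l]])
  }
  list(W = dW, b = db)
}

#' Train an autoencoder
#'
#' Minimizes the mean squared reconstruction error
#' `J = (1/N) sum ||x'_i - x_i||^2` by minibatch Adam. Training is
#' deterministic given the hyperparameter seed. The returned model carries
#' the parameters of the epoch with the lowest full-data `J` (so its final
#' logged error never exceeds the initial one) and the per-epoch training
#' log.
#'
#' @param X Sample matrix (rows = samples, columns = `spec$input_dim`
#'   features scaled to \[0, 1\]).
#' @param spec An [autoencoder_spec()].
#' @param hp A [train_hyperparams()].
#' @return A `TrainedAutoencoder`.
#' @export
train_autoencoder <- function(X, spec = autoencoder_spec(),
                              hp = train_hyperparams()) {
  stopifnot(is.matrix(X), nrow(X) >= 1)
  if (ncol(X) != spec$input_dim)
    stop_cp("sample dimension %d != spec input width %d", ncol(X), spec$input_dim)
  with_seed(hp$seed, {
    params <- ae_init_params(spec$widths)
    m <- rapply(params, function(p) p * 0, how = "replace")
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    n <- nrow(X)
    log_J <- numeric(hp$epochs + 1L)
    log_J[1] <- ae_loss(params, X, spec$output_activation)
    best <- list(J = log_J[1], params = params, epoch = 0L)
    stall <- 0L
    n_epochs_run <- 0L
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = hp$batch_size)
      for (s in starts) {
        batch <- ord[s:min(s + hp$batch_size - 1L, n)]
        g <- ae_grad(params, X[batch, , drop = FALSE], spec$output_activation)
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (part in c("W", "b")) {
          for (l in seq_along(params[[part]])) {
            m[[part]][[l]] <- beta1 * m[[part]][[l]] + (1 - beta1) * g[[part]][[l]]
            v[[part]][[l]] <- beta2 * v[[part]][[l]] + (1 - beta2) * g[[part]][[l]]^2
            params[[part]][[l]] <- params[[part]][[l]] -
              hp$learning_rate * (m[[part]][[l]] / corr1) /
              (sqrt(v[[part]][[l]] / corr2) + eps)
          }
        }
      }
      J <- ae_loss(params, X, spec$output_activation)
      if (!is.finite(J))
        stop_cp("training diverged (non-finite J at epoch %d; lr = %g)",
                epoch, hp$learning_rate)
      log_J[epoch + 1L] <- J
      n_epochs_run <- epoch
      if (J < best$J - 1e-15) {
        best <- list(J = J, params = params, epoch = epoch)
      }
      if (!is.null(hp$early_stop)) {
        if (J > best$J - hp$early_stop$min_delta) stall <- stall + 1L
        else stall <- 0L
        if (stall >= hp$early_stop$patience) break
      }
    }
    structure(list(spec = spec, hyperparams = hp,
                   params = best$params,
                   best_epoch = best$epoch,
                   training_log = log_J[seq_len(n_epochs_run + 1L)],
                   fitted_on = list(n = n, dim = ncol(X),
                                    checksum = sum(X))),
              class = "TrainedAutoencoder")
  })
}

#' @export
print.TrainedAutoencoder <- function(x, ...) {
  cat(sprintf("<TrainedAutoencoder> %s, J: %.4g -> %.4g (best epoch %d/%d)\n",
              paste(x$spec$widths, collapse = "-"),
              x$training_log[1], min(x$training_log),
              x$best_epoch, length(x$training_log) - 1L))
  invisible(x)
}

#' Encode samples into the latent space
#'
#' Returns the bottleneck-layer activations, one row per input sample, order
#' preserved. With sigmoid activations every coordinate lies in (0, 1).
#'
#' @param model A `TrainedAutoencoder`.
#' @param X Sample matrix with `spec$input_dim` columns.
#' @return Matrix of latent coordinates (`bottleneck` columns).
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "TrainedAutoencoder"), is.matrix(X))
  if (ncol(X) != model$spec$input_dim)
    stop_cp("sample dimension %d != model input width %d",
            ncol(X), model$spec$input_dim)
  A <- ae_forward(model$params, X, model$spec$output_activation)
  A[[model$spec$bottleneck_layer + 1L]]
}

#' Reconstruct samples through the autoencoder
#'
#' @inheritParams encode
#' @return Matrix of reconstructions, same shape as `X`.
#' @export
reconstruct <- function(model, X) {
  stopifnot(inherits(model, "TrainedAutoencoder"), is.matrix(X))
  if (ncol(X) != model$spec$input_dim)
    stop_cp("sample dimension %d != model input width %d",
            ncol(X), model$spec$input_dim)
  A <- ae_forward(model$params, X, model$spec$output_activation)
  A[[length(A)]]
}

#' Mean reconstruction error
#'
#' `J = (1/N) sum_i ||x'_i - x_i||^2`, the quantity the autoencoder is
#' trained to minimize and the anomaly-detection score.
#'
#' @inheritParams encode
#' @param per_sample If `TRUE`, return the vector of per-sample squared
#'   errors instead of their mean.
#' @return Scalar `J >= 0`, or a per-sample vector.
#' @export
reconstruction_error <- function(model, X, per_sample = FALSE) {
  stopifnot(nrow(X) >= 1)
  R <- reconstruct(model, X)
  errs <- rowSums((R - X)^2)
  if (per_sample) errs else mean(errs)
}

#' Reconstruction error as a function of bottleneck dimension
#'
#' Trains one independent autoencoder per requested bottleneck width (same
#' seed schedule and hyperparameters) and reports the final reconstruction
#' error for each: the diagnostic curve used to confirm anomalous recordings.
#'
#' @param X Sample matrix.
#' @param dims Bottleneck dimensions to sweep (nonempty).
#' @param hidden Encoder hidden widths.
#' @param hp A [train_hyperparams()].
#' @param output_activation Passed to [autoencoder_spec()].
#' @return Data frame with columns `dim` and `J`.
#' @export
bottleneck_sweep <- function(X, dims, hidden = c(100, 50),
                             hp = train_hyperparams(),
                             output_activation = "sigmoid") {
  if (length(dims) == 0) stop_cp("dims must be nonempty")
  J <- vapply(dims, function(d) {
    spec <- autoencoder_spec(input_dim = ncol(X), hidden = hidden,
                             bottleneck = d,
                             output_activation = output_activation)
    model <- train_autoencoder(X, spec, hp)
    min(model$training_log)
  }, numeric(1))
  data.frame(dim = dims, J = J)
}
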