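#' Multi-layer perceptron specification
#'
#' Architecture of the spectrum-to-concentration regressor: a fully
#' connected network with `n_in` input nodes (one per grid point), one or
#' more hidden layers, and `n_out` linear output nodes, one per analyte.
#' Outputs carry no activation and no non-negativity clamp, so predictions
#' are unconstrained concentrations in mM. The default mirrors the
#' reference architecture (39,500 inputs, one 200-node hidden layer, 8
#' outputs); `n_out` is freely configurable (e.g. 18 for a lipid-parameter
#' panel).
#'
#' @param n_in Input dimension (grid points).
#' @param hidden Integer vector of hidden-layer widths, default `200`.
#' @param n_out Output dimension (analytes), default 8.
#' @param activation Hidden activation, `"relu"` (default) or
#'   `"identity"` (useful for analytically solvable toy models).
#' @param seed Integer seed for deterministic weight initialization.
#' @return An object of class `mlp_spec`.
#' @export
model_spec <- function(n_in = 39500, hidden = 200, n_out = 8,
                       activation = c("relu", "identity"), seed = 1) {
  activation <- match.arg(activation)
  stopifnot(n_in >= 1, n_out >= 1, all(hidden >= 1))
  structure(list(n_in = as.integer(n_in), hidden = as.integer(hidden),
                 n_out = as.integer(n_out), activation = activation,
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Initialize an MLP
#'
#' Deterministic given `spec$seed`. Weights and biases of each layer are
#' drawn from the scaled-uniform fan-in scheme U(-1/sqrt(fan_in),
#' 1/sqrt(fan_in)).
#'
#' @param spec An [model_spec()].
#' @return An object of class `mlp_model` with per-layer weight matrices
#'   `W` (fan_in x fan_out) and bias vectors `b`, the spec, a
#'   `norm_constant` (1 until trained), and an empty training log.
#' @export
init_model <- function(spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  dims <- c(spec$n_in, spec$hidden, spec$n_out)
  with_seed(spec$seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1)) {
      r <- 1 / sqrt(dims[l])
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -r, r), dims[l])
      b[[l]] <- stats::runif(dims[l + 1], -r, r)
    }
  })
  structure(list(spec = spec, W = W, b = b, norm_constant = 1,
                 training_log = NULL),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s, %s activation, norm_constant %.4g%s\n",
              paste(c(x$spec$n_in, x$spec$hidden, x$spec$n_out),
                    collapse = "-"),
              x$spec$activation, x$norm_constant,
              if (is.null(x$training_log)) " (untrained)" else
                sprintf(", best test loss %.3g",
                        min(x$training_log$test_loss))))
  invisible(x)
}

.activate <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else z
}

## forward pass over a batch (rows = samples); returns activations when
## keep_hidden, for use by the backward pass and the attribution engine
.forward_batch <- function(model, X, keep_hidden = FALSE) {
  act <- model$spec$activation
  L <- length(model$W)
  Z <- list(); H <- list()
  a <- X
  for (l in seq_len(L - 1)) {
    Z[[l]] <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    H[[l]] <- .activate(Z[[l]], act)
    a <- H[[l]]
  }
  out <- sweep(a %*% model$W[[L]], 2, model$b[[L]], "+")
  if (keep_hidden) list(out = out, Z = Z, H = H) else out
}

#' Predict analyte concentrations from a spectrum
#'
#' @param model A (typically trained) `mlp_model`.
#' @param x An [nmr_spectrum()], a numeric vector, or a matrix with one
#'   sample per row.
#' @param normalized Set `TRUE` when `x` is already divided by the model's
#'   `norm_constant`; raw spectra (the default) are normalized first.
#' @return Numeric vector of `n_out` concentrations in mM (or a matrix for
#'   batched input).
#' @export
forward <- function(model, x, normalized = FALSE) {
  stopifnot(inherits(model, "mlp_model"))
  if (inherits(x, "nmr_spectrum")) x <- x$intensities
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else as.matrix(x)
  if (ncol(X) != model$spec$n_in)
    stop(sprintf("input has %d features, model expects %d",
                 ncol(X), model$spec$n_in))
  if (!normalized) X <- X / model$norm_constant
  out <- .forward_batch(model, X)
  if (single) out[1, ] else out
}

#' Training configuration
#'
#' Mean-squared-error loss minimized with the Adam optimizer
#' (adaptive-moment gradient descent), mini-batches of `batch_size`, the
#' test split evaluated every epoch, and the checkpoint with the lowest
#' test loss returned.
#'
#' @param batch_size Mini-batch size, default 128.
#' @param max_epochs Number of epochs.
#' @param lr Base learning rate, default 1e-3.
#' @param lr_schedule `"cosine"` (decay to 0 over `max_epochs`) or
#'   `"constant"`.
#' @param beta1,beta2,eps Adam moment-decay and stabilization constants.
#' @param seed Seed for shuffling (training is deterministic given model
#'   seed + this seed + the dataset).
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128, max_epochs = 100, lr = 1e-3,
                         lr_schedule = c("cosine", "constant"),
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(batch_size >= 1, max_epochs >= 1, lr > 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 lr_schedule = lr_schedule, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Train an MLP on a labeled dataset
#'
#' Minimizes the MSE between predictions and ground-truth concentrations
#' on the train split with Adam, evaluating the test split after every
#' epoch. The returned model carries the weights of the epoch with the
#' lowest test loss, the dataset's normalization constant, and the full
#' per-epoch loss log. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model An `mlp_model` (initialized, or previously trained).
#' @param dataset An `nmr_dataset` (already normalized).
#' @param config A [train_config()].
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return The trained `mlp_model`.
#' @export
train <- function(model, dataset, config, verbose = 0) {
  stopifnot(inherits(model, "mlp_model"), inherits(dataset, "nmr_dataset"),
            inherits(config, "train_config"))
  if (ncol(dataset$spectra) != model$spec$n_in)
    stop("dataset grid does not match model input layer")
  if (ncol(dataset$concentrations) != model$spec$n_out)
    stop("dataset panel does not match model output layer")
  Xtr <- dataset$spectra[dataset$split == "train", , drop = FALSE]
  Ytr <- dataset$concentrations[dataset$split == "train", , drop = FALSE]
  Xte <- dataset$spectra[dataset$split == "test", , drop = FALSE]
  Yte <- dataset$concentrations[dataset$split == "test", , drop = FALSE]
  if (nrow(Xtr) == 0 || nrow(Xte) == 0) stop("dataset must have train and test splits")

  relu <- model$spec$activation == "relu"
  ## the compiled epoch step updates these in place, so take private
  ## copies that do not alias the caller's model
  W <- lapply(model$W, function(w) w + 0)
  b <- lapply(model$b, function(x) x + 0)
  mW <- lapply(W, function(w) w * 0); vW <- lapply(W, function(w) w * 0)
  mb <- lapply(b, function(x) x * 0); vb <- lapply(b, function(x) x * 0)
  n_batches <- ceiling(nrow(Xtr) / config$batch_size)
  best <- Inf
  bestW <- lapply(W, function(w) w + 0)
  bestb <- lapply(b, function(x) x + 0)
  log_tr <- numeric(config$max_epochs); log_te <- numeric(config$max_epochs)

  with_seed(config$seed, {
    for (ep in seq_len(config$max_epochs)) {
      lr <- if (config$lr_schedule == "cosine")
        config$lr * 0.5 * (1 + cos(pi * ep / config$max_epochs))
      else config$lr
      ord <- sample.int(nrow(Xtr))
      tr_loss <- mlp_train_epoch(Xtr, Ytr, ord, config$batch_size,
                                 W, b, mW, vW, mb, vb,
                                 lr, config$beta1, config$beta2, config$eps,
                                 (ep - 1L) * n_batches, relu)
      if (is.na(tr_loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", ep))
      log_tr[ep] <- tr_loss
      te_loss <- mean((mlp_forward_cpp(Xte, W, b, relu) - Yte)^2)
      log_te[ep] <- te_loss
      if (te_loss < best) {
        best <- te_loss
        bestW <- lapply(W, function(w) w + 0)
        bestb <- lapply(b, function(x) x + 0)
      }
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %d: train %.4g, test %.4g (best %.4g)",
                        ep, log_tr[ep], te_loss, best))
    }
  })
  model$W <- bestW
  model$b <- bestb
  model$norm_constant <- dataset$norm_constant
  model$training_log <- data.frame(epoch = seq_len(config$max_epochs),
                                   train_loss = log_tr, test_loss = log_te)
  model
}

#' Gradient of one output node with respect to the input
#'
#' Exact gradient of `F_node(x)` in normalized-input coordinates, computed
#' by reverse-mode differentiation of the network (for ReLU activations
#' the gradient is taken at the almost-everywhere-defined activation
#' pattern of `x`).
#'
#' @param model An `mlp_model`.
#' @param x Normalized input vector (or matrix of rows).
#' @param node Output index in 1..n_out.
#' @return Gradient vector of length `n_in` (or a matrix of per-row
#'   gradients for matrix input).
#' @export
input_gradient <- function(model, x, node) {
  stopifnot(inherits(model, "mlp_model"))
  node <- as.integer(node)
  if (node < 1 || node > model$spec$n_out) stop("invalid output node index")
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else as.matrix(x)
  G <- .input_grad_batch(model, X, node)
  if (single) G[1, ] else G
}

## per-row input gradients of output `node`, vectorized over rows of X
.input_grad_batch <- function(model, X, node) {
  act <- model$spec$activation
  L <- length(model$W)
  Zs <- vector("list", L - 1)
  a <- X
  for (l in seq_len(L - 1)) {
    Zs[[l]] <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- .activate(Zs[[l]], act)
  }
  d <- matrix(model$W[[L]][, node], nrow(X), nrow(model$W[[L]]), byrow = TRUE)
  if (L >= 2) for (l in (L - 1):1) {
    if (act == "relu") d <- d * (Zs[[l]] > 0)
    d <- d %*% t(model$W[[l]])
  }
  d
}

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds the weight arrays (`weights.rds`) and a
#' JSON manifest (spec, normalization constant, loss log).
#'
#' @param model An `mlp_model`.
#' @param dir Directory to create/read.
#' @return `write_model`: `dir` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(W = model$W, b = model$b), file.path(dir, "weights.rds"))
  jsonlite::write_json(list(spec = unclass(model$spec),
                            norm_constant = model$norm_constant,
                            training_log = model$training_log),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  wts <- readRDS(file.path(dir, "weights.rds"))
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  spec <- model_spec(m$spec$n_in, m$spec$hidden, m$spec$n_out,
                     m$spec$activation, m$spec$seed)
  structure(list(spec = spec, W = wts$W, b = wts$b,
                 norm_constant = m$norm_constant,
                 training_log = as.data.frame(m$training_log)),
            class = "mlp_model")
}
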