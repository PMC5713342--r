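# Feed-forward binary classifier: fully connected hidden layers with batch
# normalization, rectifier activation and inverted dropout, a single
# logistic output unit, clipped binary cross-entropy loss, and mini-batch
# Adam. Written in base matrix algebra; the heavy lifting is BLAS gemm.

.bn_eps <- 1e-5
.bn_momentum <- 0.9
.prob_clip <- 1e-7

#' Network configuration
#'
#' Defaults are the recommended hyperparameters for the 8120-dimensional
#' LCTD pair representation: three hidden layers of width 2048, 512 and 32,
#' dropout 0.6, learning rate 0.002, batch size 512, glorot-normal
#' initialization, Adam, batch normalization on.
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths (depth = its
#'   length; 2--9 is the explored range, 3 the default).
#' @param dropout Dropout rate in \[0, 1) applied after each hidden
#'   activation during training.
#' @param input_dropout Dropout rate in \[0, 1) applied to the input
#'   features during training (0 disables).
#' @param weight_decay L2 penalty coefficient added to the loss for every
#'   weight matrix (biases and normalization parameters are exempt).
#'   Regularizes the heavily over-parameterized first layer when training
#'   sets are small relative to the feature dimension.
#' @param learning_rate Optimizer step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Maximum training epochs.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without the mean training loss improving by more than `min_delta`.
#'   `Inf` disables early stopping.
#' @param min_delta Minimum loss improvement that resets the patience
#'   counter.
#' @param init Weight initialization: one of `"glorot_normal"`,
#'   `"glorot_uniform"`, `"lecun_uniform"`, `"uniform"`, `"normal"`.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_norm Apply batch normalization to hidden layers.
#' @param standardize Standardize every input feature to zero mean and
#'   unit variance using training-set statistics (stored on the model and
#'   re-applied at inference). The descriptor blocks mix 0--100 and 0--1
#'   scales; without this conditioning the percentage-scale columns
#'   dominate the first layer's input variance.
#' @param seed Integer seed; initialization, shuffling and dropout all
#'   flow from it.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(input_dim,
                       hidden = c(2048L, 512L, 32L),
                       dropout = 0.6,
                       input_dropout = 0,
                       weight_decay = 0,
                       learning_rate = 0.002,
                       batch_size = 512L,
                       epochs = 8L,
                       patience = 3L,
                       min_delta = 1e-3,
                       init = c("glorot_normal", "glorot_uniform",
                                "lecun_uniform", "uniform", "normal"),
                       optimizer = c("adam", "sgd"),
                       batch_norm = TRUE,
                       standardize = TRUE,
                       seed = 1L) {
  init <- match.arg(init)
  optimizer <- match.arg(optimizer)
  stopifnot(input_dim >= 1L, length(hidden) >= 1L, all(hidden >= 1L),
            dropout >= 0, dropout < 1, input_dropout >= 0,
            input_dropout < 1, weight_decay >= 0, learning_rate > 0,
            batch_size >= 1L, epochs >= 1L)
  structure(list(
    input_dim = as.integer(input_dim),
    hidden = as.integer(hidden),
    dropout = dropout,
    input_dropout = input_dropout,
    weight_decay = weight_decay,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    patience = patience,
    min_delta = min_delta,
    init = init,
    optimizer = optimizer,
    batch_norm = isTRUE(batch_norm),
    standardize = isTRUE(standardize),
    seed = as.integer(seed)
  ), class = "mlp_config")
}

.init_weights <- function(fan_in, fan_out, scheme) {
  n <- fan_in * fan_out
  w <- switch(scheme,
    glorot_normal = stats::rnorm(n, sd = sqrt(2 / (fan_in + fan_out))),
    glorot_uniform = stats::runif(n, -sqrt(6 / (fan_in + fan_out)),
                                  sqrt(6 / (fan_in + fan_out))),
    lecun_uniform = stats::runif(n, -sqrt(3 / fan_in), sqrt(3 / fan_in)),
    uniform = stats::runif(n, -0.05, 0.05),
    normal = stats::rnorm(n, sd = 0.05)
  )
  matrix(w, fan_in, fan_out)
}

#' Build an untrained network
#'
#' Allocates weights, biases and batch-normalization parameters for the
#' configured architecture: `input_dim` through the hidden widths to a
#' single logistic output unit. Hidden layers use the rectifier; weights
#' are drawn under the configured seed and scheme, so the same seed gives
#' identical initial weights.
#'
#' @param config An [mlp_config()].
#' @return An `lctd_mlp` model object (untrained).
#' @export
mlp_build <- function(config) {
  stopifnot(inherits(config, "mlp_config"))
  dims <- c(config$input_dim, config$hidden, 1L)
  n_layers <- length(dims) - 1L
  layers <- vector("list", n_layers)
  withr::with_seed(config$seed, {
    for (l in seq_len(n_layers)) {
      layer <- list(
        W = .init_weights(dims[l], dims[l + 1L], config$init),
        b = numeric(dims[l + 1L])
      )
      if (config$batch_norm && l < n_layers) {
        layer$gamma <- rep(1, dims[l + 1L])
        layer$beta <- numeric(dims[l + 1L])
        layer$running_mean <- numeric(dims[l + 1L])
        layer$running_var <- rep(1, dims[l + 1L])
      }
      layers[[l]] <- layer
    }
  })
  structure(list(
    layers = layers,
    config = config,
    history = numeric(0),
    trained = FALSE
  ), class = "lctd_mlp")
}

#' Binary cross-entropy loss
#'
#' Mean of `-[y log p + (1-y) log(1-p)]` with probabilities clipped to
#' `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param labels Integer vector in \{0, 1\}.
#' @param probabilities Predicted probabilities.
#' @return Scalar loss.
#' @export
bce_loss <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  p <- pmin(pmax(probabilities, .prob_clip), 1 - .prob_clip)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# forward pass; training = TRUE uses batch statistics, applies dropout,
# and returns the caches needed for backpropagation. The compiled kernels
# mutate matrices the pass owns (fresh gemm outputs), never user data.
.forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  n_layers <- length(model$layers)
  a <- x
  if (training && cfg$input_dropout > 0) {
    a <- dropout_copy_(x, 1 - cfg$input_dropout)
  }
  caches <- if (training) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    layer <- model$layers[[l]]
    z <- a %*% layer$W
    add_row_(z, layer$b)
    if (l == n_layers) {
      p <- stats::plogis(as.vector(z))
      if (training) caches[[l]] <- list(input = a)
      return(list(p = p, caches = caches, model = model))
    }
    xhat <- NULL
    inv_std <- NULL
    if (cfg$batch_norm) {
      if (training) {
        stats <- bn_normalize_(z, .bn_eps)  # z -> xhat in place
        xhat <- z
        inv_std <- stats$inv_std
        model$layers[[l]]$running_mean <-
          .bn_momentum * layer$running_mean + (1 - .bn_momentum) * stats$mu
        model$layers[[l]]$running_var <-
          .bn_momentum * layer$running_var + (1 - .bn_momentum) * stats$var
        h <- scale_shift_(xhat, layer$gamma, layer$beta)
      } else {
        bn_apply_(z, layer$running_mean,
                  1 / sqrt(layer$running_var + .bn_eps),
                  layer$gamma, layer$beta)
        h <- z
      }
    } else {
      h <- z
    }
    keep <- if (training && cfg$dropout > 0) 1 - cfg$dropout else 1
    f <- relu_dropout_(h, keep)  # h -> activations in place; f = d(out)/d(h)
    if (training) {
      caches[[l]] <- list(input = a, f = f, xhat = xhat, inv_std = inv_std)
    }
    a <- h
  }
  list(p = NULL, caches = caches, model = model)
}

# gradients of the mean clipped-BCE loss w.r.t. every parameter
.backward <- function(model, caches, p, y) {
  cfg <- model$config
  n_layers <- length(model$layers)
  m <- length(y)
  grads <- vector("list", n_layers)
  # output layer: d(loss)/d(logit) = (p - y)/m
  delta <- matrix((p - y) / m, ncol = 1L)
  for (l in rev(seq_len(n_layers))) {
    cache <- caches[[l]]
    layer <- model$layers[[l]]
    g <- list(W = crossprod(cache$input, delta), b = colSums(delta))
    if (l > 1L) {
      prev <- caches[[l - 1L]]
      dh <- tcrossprod(delta, layer$W) * prev$f  # rectifier + dropout
      if (cfg$batch_norm) {
        bn <- bn_backward_(dh, prev$xhat, model$layers[[l - 1L]]$gamma,
                           prev$inv_std)
        delta <- bn$dz
        grads[[l - 1L]] <- list(gamma = bn$dgamma, beta = bn$dbeta)
      } else {
        delta <- dh
      }
    }
    grads[[l]] <- c(grads[[l]], g)
  }
  grads
}

.trainable <- c("W", "b", "gamma", "beta")

.make_opt_state <- function(layers) {
  lapply(layers, function(layer) {
    lapply(layer[intersect(names(layer), .trainable)],
           function(p) list(m = p * 0, v = p * 0))
  })
}

# in-place parameter updates; weights and optimizer state are owned by
# mlp_train (deep-copied before the first step). The L2 penalty applies
# to weight matrices only.
.apply_grads <- function(model, grads, opt_state, t, lr, optimizer,
                         weight_decay = 0) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_along(model$layers)) {
    for (nm in names(opt_state[[l]])) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      wd <- if (nm == "W") weight_decay else 0
      if (optimizer == "adam") {
        st <- opt_state[[l]][[nm]]
        adam_step_(model$layers[[l]][[nm]], st$m, st$v, g,
                   lr, b1, b2, eps, t, wd)
      } else {
        sgd_step_(model$layers[[l]][[nm]], g, lr, wd)
      }
    }
  }
  invisible(model)
}

#' Train the network
#'
#' Mini-batch gradient descent on the clipped binary cross-entropy with
#' the configured optimizer (Adam by default). Rows are reshuffled every
#' epoch; dropout and batch statistics are active only during training.
#' The mean training loss per epoch is recorded in the model's history,
#' and training stops early once the loss stops improving by `min_delta`
#' for `patience` consecutive epochs.
#'
#' @param model An `lctd_mlp` from [mlp_build()].
#' @param x Numeric feature matrix (rows = examples).
#' @param y Integer labels in \{0, 1\}.
#' @param verbose Print the loss each epoch.
#' @return The trained `lctd_mlp` (with `history` filled in).
#' @export
mlp_train <- function(model, x, y, verbose = FALSE) {
  stopifnot(inherits(model, "lctd_mlp"), nrow(x) == length(y),
            all(y %in% c(0L, 1L)))
  if (ncol(x) != model$config$input_dim) {
    stop("feature dimension ", ncol(x), " does not match model input ",
         model$config$input_dim, call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    warning("training labels contain a single class; ",
            "AUC will be undefined downstream")
  }
  cfg <- model$config
  n <- nrow(x)
  if (cfg$standardize) {
    center <- colMeans(x)
    scale <- sqrt(colMeans(x^2) - center^2) * sqrt(n / max(1, n - 1))
    scale[scale < 1e-8] <- 1  # constant columns pass through untouched
    x <- scale_columns_(x, center, scale)
    model$center <- center
    model$scale <- scale
  }
  # deep-copy parameters: training updates them in place and must not
  # touch the caller's untrained model object
  model$layers <- lapply(model$layers, function(layer) {
    lapply(layer, function(p) p + 0)
  })
  opt_state <- .make_opt_state(model$layers)
  history <- numeric(0)
  t_step <- 0L
  best <- Inf
  stall <- 0L
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        fwd <- .forward(model, xb, training = TRUE)
        model <- fwd$model  # carries the updated running BN statistics
        grads <- .backward(model, fwd$caches, fwd$p, yb)
        t_step <- t_step + 1L
        .apply_grads(model, grads, opt_state, t_step,
                     cfg$learning_rate, cfg$optimizer, cfg$weight_decay)
        epoch_loss <- epoch_loss + bce_loss(yb, fwd$p) * length(idx)
      }
      epoch_loss <- epoch_loss / n
      history <- c(history, epoch_loss)
      if (verbose) message(sprintf("epoch %d: loss %.5f", epoch, epoch_loss))
      if (epoch_loss < best - cfg$min_delta) {
        best <- epoch_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict interaction probabilities
#'
#' Deterministic inference pass: dropout disabled, batch normalization
#' uses the running statistics accumulated during training. Results are
#' identical whether rows are scored one at a time or all at once.
#'
#' @param object A trained `lctd_mlp`.
#' @param newdata Numeric feature matrix (or single feature vector).
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict.lctd_mlp <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$config$input_dim) {
    stop("feature dimension ", ncol(newdata),
         " does not match model input ", object$config$input_dim,
         call. = FALSE)
  }
  if (!is.null(object$center)) {
    newdata <- scale_columns_(newdata, object$center, object$scale)
  }
  .forward(object, newdata, training = FALSE)$p
}

#' @export
print.lctd_mlp <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "feed-forward PPI classifier: %d -> %s -> 1 (%strained)\n",
    cfg$input_dim, paste(cfg$hidden, collapse = " -> "),
    if (x$trained) "" else "un"
  ))
  cat(sprintf("dropout %.2f, lr %g, batch %d, %s, batch_norm %s, seed %d\n",
              cfg$dropout, cfg$learning_rate, cfg$batch_size,
              cfg$optimizer, cfg$batch_norm, cfg$seed))
  if (length(x$history)) {
    cat(sprintf("trained %d epochs, final loss %.5f\n",
                length(x$history), utils::tail(x$history, 1)))
  }
  invisible(x)
}

#' Save / load a trained model
#'
#' One archive file holding weights, configuration and training history.
#'
#' @param model An `lctd_mlp`.
#' @param path File path.
#' @return `save_mlp`: `path` invisibly. `load_mlp`: the model.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "lctd_mlp"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lctd_mlp"))
  model
}
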