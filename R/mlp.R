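# Feed-forward network core shared by the noise classifier (logistic hidden
# units, softmax output, cross-entropy) and the denoising autoencoder (ReLU
# hidden units, linear output, mean squared error). Written in plain matrix
# algebra: forward h^(l) = act(h^(l-1) W^l + b^l), exact backpropagation, and
# an Adam optimizer with a per-layer trainable mask (the mask is what makes
# single-layer knowledge transfer possible).

new_mlp <- function(layers, hidden_activation, output_activation,
                    norm_stats = NULL, meta = list(), subclass = character()) {
  m <- structure(list(layers = layers,
                      hidden_activation = hidden_activation,
                      output_activation = output_activation,
                      norm_stats = norm_stats, meta = meta),
                 class = c(subclass, "eanr_mlp"))
  validate_mlp(m)
  m
}

validate_mlp <- function(model) {
  L <- length(model$layers)
  if (L < 1L) stop_invalid("model needs at least one weight layer")
  for (l in seq_len(L)) {
    W <- model$layers[[l]]$W; b <- model$layers[[l]]$b
    if (!is.matrix(W) || length(b) != ncol(W)) stop_invalid("layer %d malformed", l)
    if (!all(is.finite(W)) || !all(is.finite(b))) stop_invalid("non-finite parameters in layer %d", l)
    if (l > 1L && nrow(W) != ncol(model$layers[[l - 1L]]$W)) {
      stop_invalid("layer %d input width %d does not chain with layer %d output %d",
                   l, nrow(W), l - 1L, ncol(model$layers[[l - 1L]]$W))
    }
  }
  if (!model$hidden_activation %in% c("logistic", "relu")) stop_invalid("bad hidden activation")
  if (!model$output_activation %in% c("softmax", "linear")) stop_invalid("bad output activation")
  invisible(model)
}

#' Layer sizes of a network
#'
#' @param model An `eanr_mlp`.
#' @return Integer vector `c(input_dim, hidden..., output_dim)`.
#' @export
layer_sizes <- function(model) {
  c(nrow(model$layers[[1L]]$W),
    vapply(model$layers, function(l) ncol(l$W), 0L))
}

#' @export
print.eanr_mlp <- function(x, ...) {
  cat(sprintf("<%s> dims [%s], %s hidden / %s output, %s parameters%s\n",
              class(x)[1L], paste(layer_sizes(x), collapse = ","),
              x$hidden_activation, x$output_activation,
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$norm_stats)) " (no norm stats)" else ""))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sum over layers of `nrow(W) * ncol(W) + length(b)`.
#'
#' @param model An `eanr_mlp` (classifier or denoiser).
#' @return Exact integer count.
#' @examples
#' count_parameters(nc_init(c(13, 100, 100, 100, 12), seed = 1)) # 22812
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "eanr_mlp"))
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), 0))
}

act_fun <- function(name) {
  switch(name,
         logistic = function(z) 1 / (1 + exp(-z)),
         relu = function(z) pmax(z, 0),
         linear = identity,
         softmax = softmax_rows,
         stop_invalid("unknown activation '%s'", name))
}

# derivative expressed in terms of the activation value
act_deriv <- function(name, a) {
  switch(name,
         logistic = a * (1 - a),
         relu = (a > 0) * 1,
         stop_invalid("no derivative for activation '%s'", name))
}

# Row-wise softmax with max subtraction for overflow safety.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Forward pass through a network
#'
#' Applies `h^(l) = act(h^(l-1) %*% W^l + b^l)` layer by layer. Softmax rows
#' are computed with max subtraction and sum to one.
#'
#' @param model An `eanr_mlp`.
#' @param inputs Numeric matrix, one row per sample; width must match the
#'   model's input dimension. A vector is treated as a single row.
#' @param return_hidden If `TRUE`, also return every layer's activations.
#' @return The output matrix, or (with `return_hidden`) a list
#'   `list(output, hidden)` where `hidden[[l]]` is the activation after weight
#'   layer `l`.
#' @export
mlp_forward <- function(model, inputs, return_hidden = FALSE) {
  stopifnot(inherits(model, "eanr_mlp"))
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1L)
  if (ncol(inputs) != nrow(model$layers[[1L]]$W)) {
    stop_invalid("input width %d does not match model input %d",
                 ncol(inputs), nrow(model$layers[[1L]]$W))
  }
  L <- length(model$layers)
  hid <- act_fun(model$hidden_activation)
  out <- act_fun(model$output_activation)
  h <- inputs
  hs <- if (return_hidden) vector("list", L)
  for (l in seq_len(L)) {
    z <- add_bias(h %*% model$layers[[l]]$W, model$layers[[l]]$b)
    h <- if (l < L) hid(z) else out(z)
    if (return_hidden) hs[[l]] <- h
  }
  if (return_hidden) list(output = h, hidden = hs) else h
}

# Loss and exact gradients. Losses:
#   xent: -mean_i log p_i[class_i]      (softmax output, one-hot targets)
#   mse:  mean_i ||yhat_i - y_i||^2     (per-sample SSE averaged over samples)
# Both give output delta = dLoss/dZ_out directly (softmax+xent simplifies to
# (P - Y)/n; linear+mse to 2(Yhat - Y)/n).
mlp_loss_grad <- function(model, X, Y, loss) {
  L <- length(model$layers)
  fw <- mlp_forward(model, X, return_hidden = TRUE)
  P <- fw$output
  n <- nrow(X)
  if (loss == "xent") {
    lval <- -mean(log(pmax(rowSums(P * Y), 1e-300)))
    delta <- (P - Y) / n
  } else {
    R <- P - Y
    lval <- sum(R^2) / n
    delta <- 2 * R / n
  }
  grads <- vector("list", L)
  for (l in L:1) {
    hin <- if (l == 1L) X else fw$hidden[[l - 1L]]
    grads[[l]] <- list(W = crossprod(hin, delta), b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(model$layers[[l]]$W)) *
        act_deriv(model$hidden_activation, fw$hidden[[l - 1L]])
    }
  }
  list(loss = lval, grads = grads)
}

mlp_loss <- function(model, X, Y, loss) {
  P <- mlp_forward(model, X)
  if (loss == "xent") -mean(log(pmax(rowSums(P * Y), 1e-300))) else sum((P - Y)^2) / nrow(X)
}

#' Optimizer settings for network training
#'
#' Adam with minibatches. `trainable_mask` is a logical vector, one entry per
#' weight layer; layers marked `FALSE` are left bit-identical by training —
#' the mechanism behind single-layer knowledge transfer. An all-`FALSE` mask
#' (or `epochs = 0`) makes training a no-op.
#'
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed Seed controlling shuffling (mandatory for reproducibility).
#' @param trainable_mask Logical per-layer mask or `NULL` (all trainable).
#' @param shuffle Shuffle sample order each epoch.
#' @return A list of class `eanr_train_cfg`.
#' @export
train_config <- function(epochs = 50L, batch_size = 128L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L, trainable_mask = NULL, shuffle = TRUE) {
  check_scalar_num(epochs, "epochs", lower = 0)
  check_scalar_num(batch_size, "batch_size", lower = 1)
  check_scalar_num(lr, "lr", lower = 0)
  check_scalar_num(seed, "seed")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed), trainable_mask = trainable_mask,
                 shuffle = isTRUE(shuffle)),
            class = "eanr_train_cfg")
}

# Minibatch Adam. X, Y: row-per-sample matrices (already normalized).
# Returns list(model, loss_history) with one mean-batch-loss entry per epoch.
mlp_train <- function(model, X, Y, cfg, loss) {
  stopifnot(inherits(cfg, "eanr_train_cfg"))
  L <- length(model$layers)
  mask <- cfg$trainable_mask %||% rep(TRUE, L)
  if (length(mask) != L || !is.logical(mask)) stop_invalid("trainable_mask must be logical of length %d", L)
  n <- nrow(X)
  if (cfg$epochs == 0L || !any(mask)) {
    return(list(model = model, loss_history = numeric(0)))
  }
  mW <- lapply(model$layers, function(l) 0 * l$W)
  vW <- mW
  mb <- lapply(model$layers, function(l) 0 * l$b)
  vb <- mb
  tstep <- 0
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      nb <- ceiling(n / cfg$batch_size)
      acc <- 0
      for (bi in seq_len(nb)) {
        rows <- ord[(((bi - 1L) * cfg$batch_size) + 1L):min(bi * cfg$batch_size, n)]
        lg <- mlp_loss_grad(model, X[rows, , drop = FALSE], Y[rows, , drop = FALSE], loss)
        if (!is.finite(lg$loss)) stop("training diverged: non-finite loss", call. = FALSE)
        acc <- acc + lg$loss
        tstep <- tstep + 1
        bc1 <- 1 - cfg$beta1^tstep
        bc2 <- 1 - cfg$beta2^tstep
        for (l in which(mask)) {
          g <- lg$grads[[l]]
          mW[[l]] <- cfg$beta1 * mW[[l]] + (1 - cfg$beta1) * g$W
          vW[[l]] <- cfg$beta2 * vW[[l]] + (1 - cfg$beta2) * g$W^2
          mb[[l]] <- cfg$beta1 * mb[[l]] + (1 - cfg$beta1) * g$b
          vb[[l]] <- cfg$beta2 * vb[[l]] + (1 - cfg$beta2) * g$b^2
          model$layers[[l]]$W <- model$layers[[l]]$W -
            cfg$lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + cfg$eps)
          model$layers[[l]]$b <- model$layers[[l]]$b -
            cfg$lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + cfg$eps)
        }
      }
      history[ep] <- acc / nb
    }
  })
  list(model = model, loss_history = history)
}

# He-scaled normal init (ReLU nets) or Glorot-scaled uniform init (logistic
# nets); biases start at zero in both schemes.
init_layers <- function(dims, seed, scheme = c("glorot_uniform", "he_normal")) {
  scheme <- match.arg(scheme)
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fi <- dims[l]; fo <- dims[l + 1L]
      W <- if (scheme == "glorot_uniform") {
        lim <- sqrt(6 / (fi + fo))
        matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
      } else {
        matrix(stats::rnorm(fi * fo, sd = sqrt(2 / fi)), fi, fo)
      }
      list(W = W, b = numeric(fo))
    })
  })
}
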