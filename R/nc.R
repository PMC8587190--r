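# Noise classifier: MFCC frames -> softmax posterior over noise classes,
# averaged to one utterance-level decision, gated by a confidence threshold
# that routes between the noise-dependent and noise-independent denoisers.

#' Initialize a noise-classifier network
#'
#' Logistic hidden units and a softmax output. Weights use a seeded
#' Glorot-scaled uniform initializer; biases start at zero. The default
#' architecture is three 100-unit hidden layers over 13 MFCCs with one output
#' per noise class.
#'
#' @param sizes Integer vector of layer widths, input first, output (number of
#'   classes) last; at least two entries, all positive.
#' @param seed Integer seed for the initializer.
#' @return An `eanr_nc` model (an [`eanr_mlp`][mlp_forward]).
#' @examples
#' m <- nc_init(c(13, 100, 100, 100, 12), seed = 1)
#' count_parameters(m)
#' @export
nc_init <- function(sizes = c(13, 100, 100, 100, 12), seed = 1L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L || any(sizes < 1L)) stop_invalid("`sizes` needs >= 2 positive entries")
  new_mlp(init_layers(sizes, seed, "glorot_uniform"),
          hidden_activation = "logistic", output_activation = "softmax",
          meta = list(sizes = sizes, seed = as.integer(seed)),
          subclass = "eanr_nc")
}

# Stack per-utterance MFCC matrices into one frame matrix with frame labels.
stack_mfcc <- function(feats, labels) {
  if (is.matrix(feats)) {
    if (length(labels) != nrow(feats)) stop_invalid("need one label per frame")
    return(list(X = feats, y = as.integer(labels)))
  }
  mats <- lapply(feats, function(f) if (inherits(f, "eanr_mfcc")) f$coeffs else f)
  if (length(labels) != length(mats)) stop_invalid("need one label per utterance")
  X <- do.call(rbind, mats)
  y <- rep(as.integer(labels), vapply(mats, nrow, 0L))
  list(X = X, y = y)
}

#' Train the noise classifier
#'
#' Minimizes softmax cross-entropy against one-hot noise-class labels with
#' minibatch Adam. Frames inherit their utterance's class. Input features are
#' z-score normalized; the normalization statistics are stored in the model
#' and re-applied at classification time.
#'
#' @param model An `eanr_nc` from [nc_init()].
#' @param feats Either a single frame matrix, or a list of per-utterance
#'   [mfcc_extract()] results (or matrices).
#' @param labels Class ids in `0..K-1`: one per frame if `feats` is a matrix,
#'   one per utterance if a list.
#' @param cfg A [train_config()].
#' @return `list(model, loss_history)`.
#' @export
nc_train <- function(model, feats, labels, cfg = train_config()) {
  stopifnot(inherits(model, "eanr_nc"))
  d <- stack_mfcc(feats, labels)
  K <- ncol(model$layers[[length(model$layers)]]$W)
  if (length(unique(d$y)) < 2L) stop_invalid("training data must contain >= 2 classes")
  if (any(d$y < 0L | d$y >= K)) stop_invalid("labels must lie in 0..%d", K - 1L)
  mu <- colMeans(d$X)
  sd_ <- pmax(apply(d$X, 2L, stats::sd), 1e-8)
  model$norm_stats <- list(mean = mu, sd = sd_)
  Xn <- sweep(sweep(d$X, 2L, mu), 2L, sd_, "/")
  Y <- matrix(0, nrow(Xn), K)
  Y[cbind(seq_len(nrow(Xn)), d$y + 1L)] <- 1
  fit <- mlp_train(model, Xn, Y, cfg, loss = "xent")
  fit$model$meta$trained <- TRUE
  fit
}

#' Classify an utterance and route it to a denoiser
#'
#' Per-frame softmax posteriors are averaged over the utterance; the predicted
#' class is the argmax of the mean posterior (ties break to the lowest class
#' id) and the confidence is that maximum. The noise-dependent model for the
#' predicted class is chosen iff `confidence >= threshold`; otherwise the
#' noise-independent model is chosen (the prediction is still reported).
#'
#' @param model A trained `eanr_nc`.
#' @param feats An [mfcc_extract()] result or a frame matrix (>= 1 frame).
#' @param threshold Confidence threshold in \[0, 1\] (default 0.9).
#' @return An `eanr_routing` object: `predicted_class`, `confidence`,
#'   `chosen_model` (`list(kind = "ND"|"NI", class_id)`), and
#'   `per_frame_posteriors`.
#' @export
classify_utterance <- function(model, feats, threshold = 0.9) {
  stopifnot(inherits(model, "eanr_nc"))
  check_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  X <- if (inherits(feats, "eanr_mfcc")) feats$coeffs else feats
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) < 1L) stop_invalid("empty feature matrix")
  if (is.null(model$norm_stats)) stop_invalid("model has no normalization stats; train it first")
  Xn <- sweep(sweep(X, 2L, model$norm_stats$mean), 2L, model$norm_stats$sd, "/")
  P <- mlp_forward(model, Xn)
  pbar <- colMeans(P)
  cls <- which.max(pbar) - 1L # ties -> lowest id
  conf <- pbar[cls + 1L]
  nd <- conf >= threshold
  structure(list(predicted_class = cls,
                 confidence = unname(conf),
                 chosen_model = list(kind = if (nd) "ND" else "NI",
                                     class_id = if (nd) cls else NA_integer_),
                 per_frame_posteriors = P),
            class = "eanr_routing")
}

#' @export
print.eanr_routing <- function(x, ...) {
  cat(sprintf("<eanr_routing> class %d (confidence %.3f) -> %s%s\n",
              x$predicted_class, x$confidence, x$chosen_model$kind,
              if (x$chosen_model$kind == "ND") sprintf("(%d)", x$chosen_model$class_id) else ""))
  invisible(x)
}
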