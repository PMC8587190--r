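# Deep denoising autoencoder: LPS-to-LPS regression with ReLU hidden units
# and a linear output. One fully trained noise-independent (NI) model serves
# as the base; noise-dependent (ND) variants are derived by knowledge
# transfer, retraining exactly one weight layer per noise class. The
# TransferStore holds only those substituted layers — it IS the entire
# noise-dependent footprint of the deployed system.

#' Default denoiser layer dimensions
#'
#' Five weight layers over `bins`-dimensional LPS frames with equal hidden
#' widths: `c(bins, width, width, width, width, bins)`. The default width of
#' 256 keeps a bank of thirteen such models (twelve noise-dependent plus one
#' noise-independent) at roughly 4.3 million parameters — the scale of the
#' deployment this scheme was designed to shrink.
#'
#' @param bins LPS bins (default 257 = 512-point FFT).
#' @param width Hidden-layer width.
#' @param n_hidden Number of hidden layers (weight layers = `n_hidden + 1`).
#' @return Integer vector of layer dimensions.
#' @export
ddae_default_dims <- function(bins = 257L, width = 256L, n_hidden = 4L) {
  as.integer(c(bins, rep(width, n_hidden), bins))
}

#' Initialize a denoising autoencoder
#'
#' Seeded He-scaled normal initialization, ReLU hidden activations, linear
#' output. Input and output widths must match (the model maps noisy LPS
#' frames to clean LPS frames of the same bin count).
#'
#' @param dims Layer dimensions, first equal to last, at least four entries
#'   (three weight layers).
#' @param seed Integer seed.
#' @return An `eanr_ddae` model.
#' @examples
#' ddae_init(c(8, 4, 4, 4, 4, 8), seed = 1)
#' @export
ddae_init <- function(dims = ddae_default_dims(), seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) < 4L) stop_invalid("denoiser needs >= 3 weight layers")
  if (dims[1L] != dims[length(dims)]) {
    stop_invalid("input dim %d must equal output dim %d", dims[1L], dims[length(dims)])
  }
  if (any(dims < 1L)) stop_invalid("all dims must be positive")
  new_mlp(init_layers(dims, seed, "he_normal"),
          hidden_activation = "relu", output_activation = "linear",
          meta = list(dims = dims, seed = as.integer(seed),
                      L = length(dims) - 1L),
          subclass = "eanr_ddae")
}

as_lps_matrix <- function(x) {
  if (inherits(x, "eanr_frames")) x$lps else if (is.matrix(x)) x else
    stop_invalid("expected an eanr_frames object or an LPS matrix")
}

ddae_normalize <- function(model, X) {
  ns <- model$norm_stats %||% list(mean = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  sweep(sweep(X, 2L, ns$mean), 2L, ns$sd, "/")
}

ddae_denormalize <- function(model, X) {
  ns <- model$norm_stats %||% list(mean = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  sweep(sweep(X, 2L, ns$sd, "*"), 2L, ns$mean, "+")
}

#' Train a denoising autoencoder on paired LPS frames
#'
#' Minimizes the mean (over frames) squared error between the network output
#' and the clean LPS target, over the trainable layers only: layers masked
#' out in `cfg$trainable_mask` are bit-identical before and after — the
#' conservation property knowledge transfer relies on. On first training the
#' model stores per-bin z-score statistics of the noisy input, applied to
#' both input and target (and inverted at enhancement time).
#'
#' @param model An `eanr_ddae`.
#' @param noisy_lps,clean_lps Frame-aligned LPS matrices (or
#'   [stft_analyze()] results) of identical shape.
#' @param cfg A [train_config()].
#' @return `list(model, loss_history)` (loss in normalized units).
#' @export
ddae_train <- function(model, noisy_lps, clean_lps, cfg = train_config()) {
  stopifnot(inherits(model, "eanr_ddae"))
  X <- as_lps_matrix(noisy_lps)
  Y <- as_lps_matrix(clean_lps)
  if (!identical(dim(X), dim(Y))) stop_invalid("noisy/clean LPS matrices are misaligned")
  if (ncol(X) != layer_sizes(model)[1L]) {
    stop_invalid("LPS width %d does not match model input %d", ncol(X), layer_sizes(model)[1L])
  }
  if (is.null(model$norm_stats)) {
    model$norm_stats <- list(mean = colMeans(X), sd = pmax(apply(X, 2L, stats::sd), 1e-8))
  }
  fit <- mlp_train(model, ddae_normalize(model, X), ddae_normalize(model, Y), cfg, loss = "mse")
  fit$model$meta$trained <- TRUE
  fit
}

#' Enhance noisy LPS frames
#'
#' Normalizes the input with the model's stored statistics, runs the forward
#' pass, and de-normalizes back to LPS units.
#'
#' @param model An `eanr_ddae`.
#' @param noisy An [stft_analyze()] result or LPS matrix.
#' @return Enhanced LPS matrix, frame-aligned with the input.
#' @export
ddae_enhance <- function(model, noisy) {
  stopifnot(inherits(model, "eanr_ddae"))
  X <- as_lps_matrix(noisy)
  out <- ddae_denormalize(model, mlp_forward(model, ddae_normalize(model, X)))
  if (!all(is.finite(out))) stop("non-finite enhancement output", call. = FALSE)
  out
}

# ---------------------------------------------------------------------------
# Knowledge transfer
# ---------------------------------------------------------------------------

# Cheap content fingerprint of a model's parameters: architecture plus exact
# sums of the weights. Used to detect a stale TransferStore (a store derived
# from a different base model must not be applied).
model_fingerprint <- function(model) {
  acc1 <- 0; acc2 <- 0
  for (l in model$layers) {
    acc1 <- acc1 + sum(l$W) + sum(l$b)
    acc2 <- acc2 + sum(l$W^2) + sum(l$b^2)
  }
  paste(paste(layer_sizes(model), collapse = "x"),
        sprintf("%.17g|%.17g", acc1, acc2), sep = "#")
}

#' Create an empty transfer store for a base model
#'
#' The store records the base (noise-independent) model's fingerprint and the
#' substituted weight-layer index, and maps noise-class ids to the retrained
#' `(W, b)` of that single layer.
#'
#' @param ni_model The trained noise-independent `eanr_ddae`.
#' @param substituted_index Weight-layer index in `1..L` to substitute
#'   (default 3, the middle weight layer of the default five-layer denoiser:
#'   substituting it gave the most robust matched-noise adaptation in the
#'   package's own sweeps).
#' @return An `eanr_store`.
#' @export
transfer_store <- function(ni_model, substituted_index = 3L) {
  stopifnot(inherits(ni_model, "eanr_ddae"))
  L <- length(ni_model$layers)
  substituted_index <- as.integer(substituted_index)
  if (substituted_index < 1L || substituted_index > L) {
    stop_invalid("substituted_index must be in 1..%d", L)
  }
  structure(list(base_fingerprint = model_fingerprint(ni_model),
                 substituted_index = substituted_index,
                 layer_dim = dim(ni_model$layers[[substituted_index]]$W),
                 entries = list()),
            class = "eanr_store")
}

#' @export
print.eanr_store <- function(x, ...) {
  cat(sprintf("<eanr_store> layer %d (%d x %d), %d class entr%s\n",
              x$substituted_index, x$layer_dim[1L], x$layer_dim[2L],
              length(x$entries), if (length(x$entries) == 1L) "y" else "ies"))
  invisible(x)
}

#' Derive a noise-dependent layer by single-layer fine-tuning
#'
#' Starts from the noise-independent model's parameters and runs [ddae_train()]
#' on matched-noise data with only `substituted_index` trainable. Returns just
#' that layer's `(W, b)` plus provenance; the base model is never mutated.
#' Fine-tuning defaults are deliberately gentle (10 epochs at a learning rate
#' ten times below base training): the adaptation is a small correction, not a
#' retraining.
#'
#' @param ni_model The trained noise-independent `eanr_ddae`.
#' @param noisy_lps,clean_lps Matched-noise training pairs (one noise class).
#' @param substituted_index Weight-layer index in `1..L`.
#' @param cfg A [train_config()]; its `trainable_mask` is overridden.
#' @return An `eanr_nd_entry`: `W`, `b`, `substituted_index`, `loss_history`.
#' @export
derive_nd_layer <- function(ni_model, noisy_lps, clean_lps, substituted_index = 3L,
                            cfg = train_config(epochs = 10L, lr = 1e-4)) {
  stopifnot(inherits(ni_model, "eanr_ddae"))
  L <- length(ni_model$layers)
  substituted_index <- as.integer(substituted_index)
  if (substituted_index < 1L || substituted_index > L) {
    stop_invalid("substituted_index must be in 1..%d", L)
  }
  cfg$trainable_mask <- seq_len(L) == substituted_index
  fit <- ddae_train(ni_model, noisy_lps, clean_lps, cfg)
  lay <- fit$model$layers[[substituted_index]]
  structure(list(W = lay$W, b = lay$b,
                 substituted_index = substituted_index,
                 epochs = cfg$epochs,
                 loss_history = fit$loss_history),
            class = "eanr_nd_entry")
}

#' Add or fetch a class entry in a transfer store
#'
#' @param store An `eanr_store`.
#' @param class_id Noise-class id (0-based).
#' @param entry An `eanr_nd_entry` from [derive_nd_layer()].
#' @return `store_set` returns the updated store; `store_get` the entry;
#'   `store_classes` the sorted integer ids present.
#' @export
store_set <- function(store, class_id, entry) {
  stopifnot(inherits(store, "eanr_store"), inherits(entry, "eanr_nd_entry"))
  if (entry$substituted_index != store$substituted_index) {
    stop_invalid("entry substitutes layer %d but store holds layer %d",
                 entry$substituted_index, store$substituted_index)
  }
  if (!identical(dim(entry$W), store$layer_dim)) stop_invalid("entry shape mismatch")
  store$entries[[as.character(as.integer(class_id))]] <- entry
  store
}

#' @rdname store_set
#' @export
store_get <- function(store, class_id) {
  e <- store$entries[[as.character(as.integer(class_id))]]
  if (is.null(e)) stop_invalid("no entry for class %d in store", class_id)
  e
}

#' @rdname store_set
#' @export
store_classes <- function(store) sort(as.integer(names(store$entries)))

#' Compose a noise-dependent model from the base model and a store
#'
#' Returns a model equal to the noise-independent base with exactly the
#' stored layer replaced by the class entry. Pure: neither input is mutated.
#' Errors if the store was derived from a different base model (stale store)
#' or the class is absent.
#'
#' @param ni_model The noise-independent `eanr_ddae` the store was built from.
#' @param store An `eanr_store`.
#' @param class_id Noise-class id present in the store.
#' @return The composed noise-dependent `eanr_ddae`.
#' @export
apply_transfer <- function(ni_model, store, class_id) {
  stopifnot(inherits(ni_model, "eanr_ddae"), inherits(store, "eanr_store"))
  if (!identical(model_fingerprint(ni_model), store$base_fingerprint)) {
    stop("stale transfer store: base model fingerprint does not match", call. = FALSE)
  }
  e <- store_get(store, class_id)
  nd <- ni_model
  nd$layers[[store$substituted_index]]$W <- e$W
  nd$layers[[store$substituted_index]]$b <- e$b
  nd$meta$nd_class <- as.integer(class_id)
  nd
}

#' Map the transfer index r to a weight-layer index
#'
#' The substituted layer is written `W^(L-r)` in the transfer formulation;
#' with `L = 5` and `r = 3` this is weight layer 2. Valid for `r` in
#' `1..L-1`.
#'
#' @param r Transfer index.
#' @param L Number of weight layers.
#' @return The substituted weight-layer index `L - r`.
#' @export
r_to_layer <- function(r, L = 5L) {
  r <- as.integer(r); L <- as.integer(L)
  if (any(r < 1L | r > L - 1L)) stop_invalid("r must be in 1..L-1")
  L - r
}

# ---------------------------------------------------------------------------
# Store derivation over a corpus, and the layer-substitution sweep
# ---------------------------------------------------------------------------

# Stack LPS (noisy, clean) training pairs for the given classes from a
# manifest split. Returns list(by_class = list(class -> list(noisy, clean)),
# all = list(noisy, clean)).
gather_lps <- function(manifest, stft_cfg = stft_config(), split = "train",
                       classes = NULL, snrs = NULL) {
  stopifnot(inherits(manifest, "eanr_manifest"))
  keep <- manifest$split == split
  if (!is.null(classes)) keep <- keep & manifest$class_id %in% classes
  if (!is.null(snrs)) keep <- keep & manifest$snr_db %in% snrs
  idx <- which(keep)
  if (length(idx) == 0L) stop_invalid("no manifest entries selected")
  by_class <- list()
  for (i in idx) {
    e <- resolve_entry(manifest, i)
    key <- as.character(e$class_id)
    nz <- stft_analyze(e$noisy, stft_cfg)$lps
    cl <- stft_analyze(e$clean, stft_cfg)$lps
    if (is.null(by_class[[key]])) by_class[[key]] <- list(noisy = list(), clean = list())
    by_class[[key]]$noisy[[length(by_class[[key]]$noisy) + 1L]] <- nz
    by_class[[key]]$clean[[length(by_class[[key]]$clean) + 1L]] <- cl
  }
  by_class <- lapply(by_class, function(b) {
    list(noisy = do.call(rbind, b$noisy), clean = do.call(rbind, b$clean))
  })
  list(by_class = by_class,
       all = list(noisy = do.call(rbind, lapply(by_class, `[[`, "noisy")),
                  clean = do.call(rbind, lapply(by_class, `[[`, "clean"))))
}

#' Derive a full transfer store from a corpus
#'
#' Runs [derive_nd_layer()] on the train-split mixtures of each class and
#' collects the retrained layers into one store.
#'
#' @param ni_model Trained noise-independent `eanr_ddae`.
#' @param manifest An `eanr_manifest`.
#' @param substituted_index Weight-layer index to retrain.
#' @param cfg Fine-tuning [train_config()].
#' @param stft_cfg The [stft_config()] shared by the system.
#' @param classes Class ids (default: all classes in the manifest).
#' @return An `eanr_store` with one entry per class.
#' @export
derive_store <- function(ni_model, manifest, substituted_index = 3L,
                         cfg = train_config(epochs = 10L, lr = 1e-4),
                         stft_cfg = stft_config(), classes = NULL) {
  classes <- classes %||% sort(unique(manifest$class_id))
  g <- gather_lps(manifest, stft_cfg, split = "train", classes = classes)
  store <- transfer_store(ni_model, substituted_index)
  for (cls in classes) {
    b <- g$by_class[[as.character(cls)]]
    if (is.null(b)) stop_invalid("no training data for class %d", cls)
    cfg_c <- cfg
    cfg_c$seed <- derive_seed(cfg$seed, cls)
    store <- store_set(store, cls,
                       derive_nd_layer(ni_model, b$noisy, b$clean, substituted_index, cfg_c))
  }
  store
}

#' Sweep the substituted layer across the network
#'
#' For each candidate weight layer, derives per-class noise-dependent layers
#' from the train split and scores the matched-noise test mixtures (STOI, and
#' PESQ when a backend is registered; see [eval_pesq()]), reporting one row
#' per (layer, class, SNR) cell. Deterministic given the config seeds.
#'
#' @param ni_model Trained noise-independent `eanr_ddae`.
#' @param manifest An `eanr_manifest` with train and test splits.
#' @param layers Weight-layer indices to sweep (default all, `1..L`).
#' @param cfg Fine-tuning [train_config()].
#' @param stft_cfg Shared [stft_config()].
#' @param classes Class ids (default: all in the manifest).
#' @return A data frame `layer, class_id, snr_db, mean_stoi, mean_pesq, n`.
#' @export
layer_sweep <- function(ni_model, manifest, layers = NULL,
                        cfg = train_config(epochs = 10L, lr = 1e-4),
                        stft_cfg = stft_config(), classes = NULL) {
  stopifnot(inherits(ni_model, "eanr_ddae"))
  L <- length(ni_model$layers)
  layers <- as.integer(layers %||% seq_len(L))
  if (any(layers < 1L | layers > L)) stop_invalid("layer indices must be in 1..%d", L)
  classes <- classes %||% sort(unique(manifest$class_id))
  train <- gather_lps(manifest, stft_cfg, split = "train", classes = classes)
  test_idx <- which(manifest$split == "test" & manifest$class_id %in% classes)
  if (length(test_idx) == 0L) stop_invalid("manifest has no test entries for the chosen classes")
  tests <- lapply(test_idx, function(i) {
    e <- resolve_entry(manifest, i)
    c(e, list(frames = stft_analyze(e$noisy, stft_cfg)))
  })
  pesq_fun <- getOption("eanr.pesq_backend", NULL)
  rows <- list()
  for (li in layers) {
    for (cls in classes) {
      b <- train$by_class[[as.character(cls)]]
      cfg_c <- cfg
      cfg_c$seed <- derive_seed(cfg$seed, li, cls)
      entry <- derive_nd_layer(ni_model, b$noisy, b$clean, li, cfg_c)
      st <- store_set(transfer_store(ni_model, li), cls, entry)
      nd <- apply_transfer(ni_model, st, cls)
      for (snr in sort(unique(manifest$snr_db[test_idx]))) {
        sel <- Filter(function(e) e$class_id == cls && e$snr_db == snr, tests)
        if (length(sel) == 0L) next
        st_scores <- pq_scores <- numeric(0)
        for (e in sel) {
          enh <- stft_synthesize(ddae_enhance(nd, e$frames), e$frames$phase,
                                 stft_cfg, e$frames$n_samples_original, rate = e$clean$rate)
          st_scores <- c(st_scores, eval_stoi(e$clean, enh))
          if (!is.null(pesq_fun)) pq_scores <- c(pq_scores, eval_pesq(e$clean, enh))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          layer = li, class_id = cls, snr_db = snr,
          mean_stoi = mean(st_scores),
          mean_pesq = if (length(pq_scores)) mean(pq_scores) else NA_real_,
          n = length(sel))
      }
    }
  }
  do.call(rbind, rows)
}
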