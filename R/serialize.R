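# JSON persistence for models, transfer stores and corpus manifests, plus a
# small YAML/JSON config reader. Weights are written as full-precision JSON
# arrays: portable, diffable, and adequate at these model sizes.

mat_to_list <- function(M) list(dim = dim(M), data = as.vector(M))
list_to_mat <- function(l) matrix(l$data, l$dim[1], l$dim[2])

#' Save or load a network model as JSON
#'
#' Stores the architecture, activations, normalization statistics and all
#' layer parameters at full precision.
#'
#' @param model An `eanr_mlp` (classifier or denoiser).
#' @param path File path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "eanr_mlp"))
  obj <- list(
    type = class(model)[1L],
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    norm_stats = model$norm_stats,
    meta = model$meta,
    layers = lapply(model$layers, function(l) list(W = mat_to_list(l$W), b = l$b))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- if (is.data.frame(obj$layers)) {
    lapply(seq_len(nrow(obj$layers)), function(i) {
      list(W = matrix(unlist(obj$layers$W$data[[i]]),
                      obj$layers$W$dim[[i]][1], obj$layers$W$dim[[i]][2]),
           b = as.numeric(unlist(obj$layers$b[[i]])))
    })
  } else {
    lapply(obj$layers, function(l) list(W = list_to_mat(l$W), b = as.numeric(l$b)))
  }
  ns <- obj$norm_stats
  if (!is.null(ns)) ns <- list(mean = as.numeric(ns$mean), sd = as.numeric(ns$sd))
  new_mlp(layers, obj$hidden_activation, obj$output_activation,
          norm_stats = ns, meta = as.list(obj$meta),
          subclass = setdiff(obj$type, "eanr_mlp"))
}

#' Save or load a transfer store as JSON
#'
#' @param store An `eanr_store`.
#' @param path File path.
#' @return `load_store` returns the store; `save_store` returns `path`
#'   invisibly.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "eanr_store"))
  obj <- list(base_fingerprint = store$base_fingerprint,
              substituted_index = store$substituted_index,
              layer_dim = store$layer_dim,
              entries = lapply(store$entries, function(e) {
                list(W = mat_to_list(e$W), b = e$b,
                     substituted_index = e$substituted_index, epochs = e$epochs)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(obj$entries, function(e) {
    structure(list(W = matrix(unlist(e$W$data), e$W$dim[[1]], e$W$dim[[2]]),
                   b = as.numeric(unlist(e$b)),
                   substituted_index = as.integer(e$substituted_index),
                   epochs = as.integer(e$epochs)),
              class = "eanr_nd_entry")
  })
  structure(list(base_fingerprint = obj$base_fingerprint,
                 substituted_index = as.integer(obj$substituted_index),
                 layer_dim = as.integer(unlist(obj$layer_dim)),
                 entries = entries),
            class = "eanr_store")
}

#' Save or load a corpus manifest as JSON
#'
#' The manifest (entries plus full corpus configuration, including the noise
#' bank) round-trips losslessly, so a saved manifest resolves to
#' bit-identical audio.
#'
#' @param manifest An `eanr_manifest`.
#' @param path File path.
#' @return `load_manifest` returns the manifest; `save_manifest` returns
#'   `path` invisibly.
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "eanr_manifest"))
  cfg <- attr(manifest, "cfg")
  obj <- list(entries = as.data.frame(manifest),
              cfg = list(classes = cfg$classes, snrs_train = cfg$snrs_train,
                         snrs_test = cfg$snrs_test, n_train = cfg$n_train,
                         n_test = cfg$n_test, duration_s = cfg$duration_s,
                         speech_rms = cfg$speech_rms, master_seed = cfg$master_seed,
                         speech = unclass(cfg$speech),
                         bank = lapply(cfg$bank, unclass)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  c0 <- obj$cfg
  bank <- lapply(c0$bank, function(s) {
    noise_spec(s$class_id, s$name, s$generator_kind,
               params = lapply(s$params, function(p) if (length(p) > 1L) unlist(p) else p))
  })
  sc <- c0$speech
  speech <- speech_cfg(rate = sc$rate, f0_range = unlist(sc$f0_range),
                       formant_ranges = lapply(sc$formant_ranges, unlist),
                       formant_bw = unlist(sc$formant_bw),
                       syllable_range = unlist(sc$syllable_range),
                       tilt_ref = sc$tilt_ref, noise_floor = sc$noise_floor)
  cfg <- corpus_config(bank = bank, classes = unlist(c0$classes),
                       snrs_train = unlist(c0$snrs_train),
                       snrs_test = unlist(c0$snrs_test),
                       n_train = c0$n_train, n_test = c0$n_test,
                       duration_s = c0$duration_s, speech_rms = c0$speech_rms,
                       master_seed = c0$master_seed, speech = speech)
  rows <- lapply(obj$entries, function(e) as.data.frame(e, stringsAsFactors = FALSE))
  man <- do.call(rbind, rows)
  attr(man, "cfg") <- cfg
  class(man) <- c("eanr_manifest", class(man))
  man
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
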