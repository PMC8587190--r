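# End-to-end orchestration: classify the noisy utterance, route to the
# noise-dependent composition (via the transfer store) or the
# noise-independent base, denoise the LPS frames, and reconstruct with the
# noisy phase. Plus the parameter-footprint accounting that quantifies what
# the transfer scheme saves.

#' Assemble an environment-aware noise-reduction system
#'
#' Bundles the trained noise classifier, the noise-independent denoiser, the
#' transfer store of per-class substituted layers, the routing threshold and
#' the shared STFT/MFCC configuration. The classifier's class set must cover
#' the store's classes, and the store must have been derived from this base
#' model.
#'
#' @param nc_model Trained `eanr_nc`.
#' @param ni_model Trained `eanr_ddae`.
#' @param store An `eanr_store` (or `NULL` for a noise-independent-only
#'   system).
#' @param threshold Routing confidence threshold in \[0, 1\].
#' @param stft_cfg Shared [stft_config()].
#' @param n_mfcc,n_mels MFCC settings the classifier was trained with.
#' @return An `eanr_system`.
#' @export
eanr_system <- function(nc_model, ni_model, store = NULL, threshold = 0.9,
                        stft_cfg = stft_config(), n_mfcc = 13L, n_mels = 26L) {
  stopifnot(inherits(nc_model, "eanr_nc"), inherits(ni_model, "eanr_ddae"))
  check_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  K <- ncol(nc_model$layers[[length(nc_model$layers)]]$W)
  if (layer_sizes(nc_model)[1L] != n_mfcc) {
    stop_invalid("classifier input width %d does not match n_mfcc = %d",
                 layer_sizes(nc_model)[1L], n_mfcc)
  }
  bins <- stft_cfg$fft_size %/% 2L + 1L
  if (layer_sizes(ni_model)[1L] != bins) {
    stop_invalid("denoiser input width %d does not match STFT bins %d",
                 layer_sizes(ni_model)[1L], bins)
  }
  if (!is.null(store)) {
    stopifnot(inherits(store, "eanr_store"))
    if (!identical(store$base_fingerprint, model_fingerprint(ni_model))) {
      stop("transfer store does not match the base model", call. = FALSE)
    }
    if (any(store_classes(store) >= K)) {
      stop_invalid("store has classes outside the classifier's 0..%d label space", K - 1L)
    }
  }
  structure(list(nc_model = nc_model, ni_model = ni_model, store = store,
                 threshold = threshold, stft_cfg = stft_cfg,
                 n_mfcc = as.integer(n_mfcc), n_mels = as.integer(n_mels)),
            class = "eanr_system")
}

#' @export
print.eanr_system <- function(x, ...) {
  cat(sprintf("<eanr_system> %d-class classifier, denoiser [%s], %s, threshold %.2f\n",
              ncol(x$nc_model$layers[[length(x$nc_model$layers)]]$W),
              paste(layer_sizes(x$ni_model), collapse = ","),
              if (is.null(x$store)) "no transfer store"
              else sprintf("%d-class store @ layer %d", length(x$store$entries),
                           x$store$substituted_index),
              x$threshold))
  invisible(x)
}

#' Enhance one noisy utterance through the full pipeline
#'
#' MFCC extraction -> utterance classification -> routing (noise-dependent
#' composition when the confidence clears the threshold and the class is in
#' the store, noise-independent otherwise) -> LPS denoising -> magnitude via
#' `exp(lps/2)` -> inverse STFT with the unmodified noisy phase. The output
#' has exactly the input's length; the routing decision is returned for
#' audit.
#'
#' @param sys An [eanr_system()].
#' @param noisy An `eanr_wave`.
#' @return `list(enhanced, decision)`.
#' @export
enhance_utterance <- function(sys, noisy) {
  stopifnot(inherits(sys, "eanr_system"), is_wave(noisy))
  feats <- mfcc_extract(noisy, sys$stft_cfg, n_mfcc = sys$n_mfcc, n_mels = sys$n_mels)
  decision <- classify_utterance(sys$nc_model, feats, sys$threshold)
  model <- sys$ni_model
  if (decision$chosen_model$kind == "ND" && !is.null(sys$store) &&
      decision$chosen_model$class_id %in% store_classes(sys$store)) {
    model <- apply_transfer(sys$ni_model, sys$store, decision$chosen_model$class_id)
  }
  frames <- stft_analyze(noisy, sys$stft_cfg)
  enh_lps <- ddae_enhance(model, frames)
  enhanced <- stft_synthesize(enh_lps, frames$phase, sys$stft_cfg,
                              frames$n_samples_original, rate = noisy$rate)
  list(enhanced = enhanced, decision = decision)
}

#' Parameter footprint of the transfer scheme versus explicit models
#'
#' Compares deploying `C` explicit noise-dependent denoisers plus the
#' noise-independent base (`total_full = nc + (C + 1) * ddae`) against the
#' transfer scheme (`total_transfer = nc + ddae + C * substituted_layer`).
#' The classifier is counted identically on both sides (or excluded from
#' both). With all five layers of equal size and twelve classes the ratio
#' approaches `17/65` — about a quarter — as widths grow.
#'
#' @param sys An [eanr_system()] with a populated store.
#' @param include_nc Count the classifier on both sides (default `TRUE`).
#' @return An `eanr_param_report`: per-component counts, `total_full`,
#'   `total_transfer`, `ratio`, `reduction_pct` and the incremental store
#'   size `store_params`.
#' @examples
#' \dontrun{
#' count_system_parameters(sys)
#' }
#' @export
count_system_parameters <- function(sys, include_nc = TRUE) {
  stopifnot(inherits(sys, "eanr_system"))
  if (is.null(sys$store) || length(sys$store$entries) == 0L) {
    stop_invalid("system has no populated transfer store (C = 0)")
  }
  C <- length(sys$store$entries)
  p_nc <- if (include_nc) count_parameters(sys$nc_model) else 0
  p_ddae <- count_parameters(sys$ni_model)
  lay <- sys$ni_model$layers[[sys$store$substituted_index]]
  p_layer <- length(lay$W) + length(lay$b)
  total_full <- p_nc + (C + 1) * p_ddae
  total_transfer <- p_nc + p_ddae + C * p_layer
  structure(list(n_classes = C, include_nc = include_nc,
                 nc_params = p_nc, ddae_params = p_ddae,
                 layer_params = p_layer, store_params = C * p_layer,
                 total_full = total_full, total_transfer = total_transfer,
                 ratio = total_transfer / total_full,
                 reduction_pct = 100 * (1 - total_transfer / total_full)),
            class = "eanr_param_report")
}

#' @export
print.eanr_param_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<eanr_param_report> C = %d classes%s\n",
    "  explicit models : %s parameters\n",
    "  transfer scheme : %s parameters (store: %s)\n",
    "  ratio %.4f, reduction %.2f%%\n"),
    x$n_classes, if (x$include_nc) " (classifier included)" else "",
    format(x$total_full, big.mark = ","),
    format(x$total_transfer, big.mark = ","),
    format(x$store_params, big.mark = ","),
    x$ratio, x$reduction_pct))
  invisible(x)
}

#' Train a complete system from a corpus
#'
#' Convenience orchestration: trains the noise classifier on labelled
#' noise-only clips, trains the noise-independent denoiser on all train-split
#' mixtures, derives the per-class transfer store, and assembles the system.
#' Every stage is reproducible from the supplied seeds.
#'
#' @param manifest An `eanr_manifest` from [build_corpus()].
#' @param noise_set A [build_noise_set()] result for classifier training.
#' @param nc_sizes,ddae_dims Architectures.
#' @param substituted_index Transfer layer.
#' @param threshold Routing threshold.
#' @param stft_cfg Shared [stft_config()].
#' @param nc_cfg,ni_cfg,ft_cfg [train_config()]s for the classifier, the base
#'   denoiser and the fine-tuning stage.
#' @param n_mfcc,n_mels MFCC settings.
#' @return A trained `eanr_system`.
#' @export
fit_eanr_system <- function(manifest, noise_set,
                            nc_sizes = c(13, 100, 100, 100, 12),
                            ddae_dims = ddae_default_dims(),
                            substituted_index = 3L,
                            threshold = 0.9,
                            stft_cfg = stft_config(),
                            nc_cfg = train_config(epochs = 50L, seed = 11L),
                            ni_cfg = train_config(epochs = 30L, seed = 12L),
                            ft_cfg = train_config(epochs = 10L, lr = 1e-4, seed = 13L),
                            n_mfcc = 13L, n_mels = 26L) {
  tr <- noise_set$split == "train"
  feats <- lapply(noise_set$waves[tr], mfcc_extract, cfg = stft_cfg,
                  n_mfcc = n_mfcc, n_mels = n_mels)
  nc <- nc_train(nc_init(nc_sizes, seed = nc_cfg$seed), feats,
                 noise_set$class_id[tr], nc_cfg)$model
  g <- gather_lps(manifest, stft_cfg, split = "train")
  ni <- ddae_train(ddae_init(ddae_dims, seed = ni_cfg$seed),
                   g$all$noisy, g$all$clean, ni_cfg)$model
  store <- derive_store(ni, manifest, substituted_index, ft_cfg, stft_cfg)
  eanr_system(nc, ni, store, threshold, stft_cfg, n_mfcc, n_mels)
}
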