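# A tiny trained system shared by the pipeline tests.
tiny_system <- function() {
  fixture("tiny_system", {
    cfg <- corpus_config(classes = c(0L, 9L), snrs_train = c(-1, 1),
                         snrs_test = 0, n_train = 3L, n_test = 2L,
                         duration_s = 0.6, master_seed = 21L)
    man <- build_corpus(cfg)
    ns <- build_noise_set(cfg$bank, n_train = 4L, n_test = 2L,
                          duration_s = 0.6, master_seed = 22L)
    keep <- ns$class_id %in% c(0L, 9L)
    ns <- list(waves = ns$waves[keep], class_id = ns$class_id[keep],
               split = ns$split[keep])
    sys <- fit_eanr_system(
      man, ns,
      nc_sizes = c(13, 24, 24, 12),
      ddae_dims = c(257, 16, 16, 16, 16, 257),
      substituted_index = 3L,
      nc_cfg = train_config(epochs = 15, seed = 11),
      ni_cfg = train_config(epochs = 8, seed = 12),
      ft_cfg = train_config(epochs = 2, lr = 1e-4, seed = 13))
    list(sys = sys, man = man)
  })
}

test_that("system assembly validates component compatibility", {
  fx <- tiny_system()
  sys <- fx$sys
  expect_s3_class(sys, "eanr_system")
  expect_error(eanr_system(sys$nc_model, sys$ni_model, sys$store, threshold = 2),
               "threshold")
  other <- ddae_init(c(257, 16, 16, 16, 16, 257), seed = 77)
  expect_error(eanr_system(sys$nc_model, other, sys$store), "store")
})

test_that("threshold 1 forces the noise-independent path bit-exactly", {
  fx <- tiny_system()
  e <- resolve_entry(fx$man, which(fx$man$split == "test")[1])
  sys_ni <- eanr_system(fx$sys$nc_model, fx$sys$ni_model, fx$sys$store,
                        threshold = 1)
  out <- enhance_utterance(sys_ni, e$noisy)
  expect_equal(out$decision$chosen_model$kind, "NI")
  # reference: the explicit noise-independent pipeline
  fr <- stft_analyze(e$noisy, fx$sys$stft_cfg)
  ref <- stft_synthesize(ddae_enhance(fx$sys$ni_model, fr), fr$phase,
                         fx$sys$stft_cfg, fr$n_samples_original)
  expect_identical(out$enhanced$samples, ref$samples)
  expect_length(out$enhanced$samples, length(e$noisy$samples))
})

test_that("an identity (0-epoch) store leaves the pipeline on the base model", {
  fx <- tiny_system()
  sys <- fx$sys
  st0 <- transfer_store(sys$ni_model, 3L)
  g <- eanr:::gather_lps(fx$man, sys$stft_cfg, "train", classes = c(0L, 9L))
  for (cls in c(0L, 9L)) {
    b <- g$by_class[[as.character(cls)]]
    st0 <- store_set(st0, cls, derive_nd_layer(sys$ni_model, b$noisy, b$clean,
                                               3L, train_config(epochs = 0)))
  }
  sys0 <- eanr_system(sys$nc_model, sys$ni_model, st0, threshold = 0)
  e <- resolve_entry(fx$man, which(fx$man$split == "test")[2])
  out0 <- enhance_utterance(sys0, e$noisy)
  fr <- stft_analyze(e$noisy, sys$stft_cfg)
  ref <- stft_synthesize(ddae_enhance(sys$ni_model, fr), fr$phase,
                         sys$stft_cfg, fr$n_samples_original)
  expect_equal(out0$decision$chosen_model$kind, "ND")
  expect_identical(out0$enhanced$samples, ref$samples)
})

test_that("the transfer store reproduces explicit ND models exactly", {
  fx <- tiny_system()
  sys <- fx$sys
  sys0 <- eanr_system(sys$nc_model, sys$ni_model, sys$store, threshold = 0)
  e <- resolve_entry(fx$man, which(fx$man$split == "test")[1])
  out <- enhance_utterance(sys0, e$noisy)
  expect_equal(out$decision$chosen_model$kind, "ND")
  nd <- apply_transfer(sys$ni_model, sys$store, out$decision$chosen_model$class_id)
  fr <- stft_analyze(e$noisy, sys$stft_cfg)
  ref <- stft_synthesize(ddae_enhance(nd, fr), fr$phase, sys$stft_cfg,
                         fr$n_samples_original)
  expect_identical(out$enhanced$samples, ref$samples)
})

test_that("parameter accounting matches the closed-form example", {
  ni <- ddae_init(c(8, 4, 4, 4, 4, 8), seed = 1)
  nc <- nc_init(c(13, 100, 100, 100, 12), seed = 1)
  X <- matrix(abs(stats::rnorm(80)), 10)
  st <- transfer_store(ni, 3L)
  for (cls in 0:11) {
    st <- store_set(st, cls, derive_nd_layer(ni, X, X, 3L, train_config(epochs = 0)))
  }
  sys <- eanr_system(nc, ni, st, stft_cfg = stft_config(frame_len = 14, hop = 7,
                                                        fft_size = 14))
  rep_ex <- count_system_parameters(sys, include_nc = FALSE)
  expect_equal(rep_ex$total_full, 13 * 136)
  expect_equal(rep_ex$total_transfer, 136 + 12 * 20)
  expect_equal(rep_ex$ratio, 376 / 1768, tolerance = 1e-12)
  expect_equal(rep_ex$reduction_pct, 100 * (1 - 376 / 1768), tolerance = 1e-10)
  # classifier counted identically on both sides
  rep_nc <- count_system_parameters(sys, include_nc = TRUE)
  expect_equal(rep_nc$total_full - rep_ex$total_full, 22812)
  expect_equal(rep_nc$total_transfer - rep_ex$total_transfer, 22812)
})

test_that("equal-width layers give exactly the 17/65 ratio", {
  ni <- ddae_init(rep(6L, 6), seed = 1)
  nc <- nc_init(c(2, 12), seed = 1)
  X <- matrix(abs(stats::rnorm(60)), 10)
  st <- transfer_store(ni, 3L)
  for (cls in 0:11) {
    st <- store_set(st, cls, derive_nd_layer(ni, X, X, 3L, train_config(epochs = 0)))
  }
  sys <- eanr_system(nc, ni, st, n_mfcc = 2L,
                     stft_cfg = stft_config(frame_len = 10, hop = 5, fft_size = 10))
  rep_eq <- count_system_parameters(sys, include_nc = FALSE)
  expect_equal(rep_eq$ratio, 17 / 65, tolerance = 1e-12)
})

test_that("reduction grows monotonically with the number of classes", {
  ni <- ddae_init(c(8, 4, 4, 4, 4, 8), seed = 1)
  nc <- nc_init(c(13, 5, 12), seed = 1)
  X <- matrix(abs(stats::rnorm(80)), 10)
  st <- transfer_store(ni, 3L)
  reds <- c()
  for (cls in 0:7) {
    st <- store_set(st, cls, derive_nd_layer(ni, X, X, 3L, train_config(epochs = 0)))
    sys <- eanr_system(nc, ni, st, stft_cfg = stft_config(frame_len = 14, hop = 7,
                                                          fft_size = 14))
    reds <- c(reds, count_system_parameters(sys)$reduction_pct)
  }
  expect_true(all(diff(reds) > 0))
})

test_that("an empty store refuses parameter accounting", {
  ni <- ddae_init(c(8, 4, 4, 4, 4, 8), seed = 1)
  nc <- nc_init(c(13, 5, 12), seed = 1)
  sys <- eanr_system(nc, ni, NULL, stft_cfg = stft_config(frame_len = 14, hop = 7,
                                                          fft_size = 14))
  expect_error(count_system_parameters(sys), "C = 0")
})
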