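test_that("identity-configured network is the identity on non-negative input", {
  m <- identity_ddae(4, 5)
  X <- matrix(abs(stats::rnorm(40)), 10)
  expect_equal(ddae_enhance(m, X), X, tolerance = 1e-12)
  expect_equal(dim(ddae_enhance(m, X)), dim(X))
})

test_that("a single repeated pair is overfit to near-zero error", {
  set.seed(6)
  noisy <- matrix(rep(stats::rnorm(6), each = 50), 50)
  clean <- matrix(rep(stats::rnorm(6), each = 50), 50)
  m <- ddae_init(c(6, 8, 8, 8, 6), seed = 2)
  m$norm_stats <- list(mean = rep(0, 6), sd = rep(1, 6)) # degenerate column sd
  fit <- ddae_train(m, noisy, clean,
                    train_config(epochs = 300, batch_size = 50, lr = 3e-3, seed = 3))
  expect_lt(tail(fit$loss_history, 1), 0.01 * fit$loss_history[1])
})

test_that("autoencoding uncorrupted frames reaches near-zero loss", {
  set.seed(7)
  X <- matrix(stats::rnorm(600), 100)
  fit <- ddae_train(ddae_init(c(6, 10, 10, 10, 6), seed = 1), X, X,
                    train_config(epochs = 500, batch_size = 50, lr = 1e-2, seed = 2))
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  expect_lt(tail(fit$loss_history, 1) / ncol(X), 1e-3) # per-bin normalized MSE
})

test_that("masked-out layers are conserved bit-for-bit", {
  set.seed(8)
  noisy <- matrix(stats::rnorm(300), 50)
  clean <- matrix(stats::rnorm(300), 50)
  m <- ddae_init(c(6, 5, 5, 5, 5, 6), seed = 4)
  # all-false mask: a no-op
  f <- ddae_train(m, noisy, clean,
                  train_config(epochs = 5, trainable_mask = rep(FALSE, 5)))
  expect_identical(f$model$layers, m$layers)
  # single trainable layer: exactly one (W, b) differs
  mask <- seq_len(5) == 2L
  f2 <- ddae_train(m, noisy, clean,
                   train_config(epochs = 5, trainable_mask = mask, seed = 5))
  for (l in 1:5) {
    if (l == 2L) {
      expect_false(identical(f2$model$layers[[l]], f$model$layers[[l]]))
    } else {
      expect_identical(f2$model$layers[[l]]$W, m$layers[[l]]$W)
      expect_identical(f2$model$layers[[l]]$b, m$layers[[l]]$b)
    }
  }
})

test_that("training validates alignment and widths", {
  m <- ddae_init(c(6, 5, 5, 5, 6), seed = 1)
  A <- matrix(0, 10, 6); B <- matrix(0, 9, 6)
  expect_error(ddae_train(m, A, B, train_config(epochs = 1)), "misaligned")
  expect_error(ddae_train(m, matrix(0, 10, 5), matrix(0, 10, 5),
                          train_config(epochs = 1)), "width")
})

test_that("derive_nd_layer is pure, shape-stable and the 0-epoch identity", {
  set.seed(9)
  noisy <- matrix(stats::rnorm(300), 50)
  clean <- matrix(stats::rnorm(300), 50)
  ni <- ddae_train(ddae_init(c(6, 5, 5, 5, 5, 6), seed = 1), noisy, clean,
                   train_config(epochs = 10, seed = 2))$model
  fp <- eanr:::model_fingerprint(ni)
  e0 <- derive_nd_layer(ni, noisy, clean, substituted_index = 3L,
                        cfg = train_config(epochs = 0))
  expect_identical(e0$W, ni$layers[[3]]$W)
  expect_identical(e0$b, ni$layers[[3]]$b)
  e1 <- derive_nd_layer(ni, noisy, clean, substituted_index = 3L,
                        cfg = train_config(epochs = 5, lr = 1e-3, seed = 3))
  expect_identical(dim(e1$W), dim(ni$layers[[3]]$W))
  expect_false(identical(e1$W, ni$layers[[3]]$W))
  expect_identical(eanr:::model_fingerprint(ni), fp) # never mutated
  expect_error(derive_nd_layer(ni, noisy, clean, substituted_index = 9L), "1..5")
})

test_that("apply_transfer swaps exactly the stored layer", {
  set.seed(10)
  noisy <- matrix(stats::rnorm(300), 50)
  clean <- matrix(stats::rnorm(300), 50)
  ni <- ddae_train(ddae_init(c(6, 5, 5, 5, 5, 6), seed = 1), noisy, clean,
                   train_config(epochs = 5, seed = 2))$model
  st <- transfer_store(ni, 3L)
  st <- store_set(st, 0L, derive_nd_layer(ni, noisy, clean, 3L,
                                          train_config(epochs = 3, seed = 4)))
  st <- store_set(st, 1L, derive_nd_layer(ni, noisy + 0.1, clean, 3L,
                                          train_config(epochs = 3, seed = 5)))
  nd0 <- apply_transfer(ni, st, 0L)
  for (l in c(1, 2, 4, 5)) expect_identical(nd0$layers[[l]], ni$layers[[l]])
  expect_false(identical(nd0$layers[[3]], ni$layers[[3]]))
  # two classes differ only in the substituted layer
  nd1 <- apply_transfer(ni, st, 1L)
  for (l in c(1, 2, 4, 5)) expect_identical(nd1$layers[[l]], nd0$layers[[l]])
  # 0-epoch entry composes to a model with identical outputs
  st0 <- store_set(transfer_store(ni, 3L), 7L,
                   derive_nd_layer(ni, noisy, clean, 3L, train_config(epochs = 0)))
  X <- matrix(stats::rnorm(60), 10)
  expect_identical(ddae_enhance(apply_transfer(ni, st0, 7L), X), ddae_enhance(ni, X))
  # stale store and missing class errors
  other <- ddae_init(c(6, 5, 5, 5, 5, 6), seed = 99)
  expect_error(apply_transfer(other, st, 0L), "stale")
  expect_error(store_get(st, 5L), "no entry")
  expect_equal(store_classes(st), c(0L, 1L))
})

test_that("r_to_layer maps the transfer index onto weight layers", {
  expect_equal(r_to_layer(3, 5), 2L)
  expect_equal(r_to_layer(1, 5), 4L)
  expect_error(r_to_layer(5, 5), "1..L-1")
})

test_that("layer sweep covers its grid and reduces to the base under 0 epochs", {
  cfg <- corpus_config(classes = c(0L, 9L), snrs_train = 0, snrs_test = 0,
                       n_train = 2L, n_test = 2L, duration_s = 0.6,
                       master_seed = 31L)
  man <- build_corpus(cfg)
  g <- eanr:::gather_lps(man, stft_config(), "train")
  ni <- ddae_train(ddae_init(c(257, 16, 16, 16, 16, 257), seed = 1),
                   g$all$noisy, g$all$clean,
                   train_config(epochs = 3, seed = 2))$model
  sw <- layer_sweep(ni, man, layers = 1:5, cfg = train_config(epochs = 0),
                    stft_cfg = stft_config())
  expect_equal(nrow(sw), 5 * 2 * 1)
  expect_equal(sort(unique(sw$layer)), 1:5)
  # 0-epoch fine-tunes: every layer row equals the noise-independent baseline
  for (cls in c(0L, 9L)) {
    vals <- sw$mean_stoi[sw$class_id == cls]
    expect_true(all(abs(vals - vals[1]) < 1e-12))
  }
})
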