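test_that("speech generator is deterministic, seed-sensitive and bounded", {
  w <- gen_speech_like(1.0, seed = 7)
  expect_s3_class(w, "eanr_wave")
  expect_length(w$samples, 16000L)
  expect_lte(max(abs(w$samples)), 1)
  expect_identical(w$samples, gen_speech_like(1.0, seed = 7)$samples)
  expect_false(identical(w$samples, gen_speech_like(1.0, seed = 8)$samples))
  expect_error(gen_speech_like(0, seed = 1), "duration")
  expect_error(gen_speech_like(-1, seed = 1), "duration")
})

test_that("speech has harmonic structure and syllable-rate modulation", {
  w <- fx_speech()
  lps <- stft_analyze(w)$lps
  # energy concentrated below 4 kHz (formant band) vs above 6 kHz
  f <- (0:256) * 16000 / 512
  low <- mean(lps[, f > 100 & f < 4000])
  high <- mean(lps[, f > 6000])
  expect_gt(low - high, 3)
  # amplitude envelope varies at syllable rate: frame RMS has real dynamics
  env <- apply(matrix(w$samples[1:15872], 256), 2, function(x) sqrt(mean(x^2)))
  expect_gt(max(env) / (min(env) + 1e-9), 3)
})

test_that("noise generators are deterministic and hit their RMS target", {
  bank <- noise_bank()
  expect_length(bank, 12L)
  expect_identical(vapply(bank, function(s) s$class_id, 0L), 0:11)
  for (s in bank[c(1, 3, 7, 9, 10)]) {
    z <- gen_noise(s, 0.5, seed = 4)
    expect_identical(z$samples, gen_noise(s, 0.5, seed = 4)$samples)
    expect_equal(wave_rms(z), 0.05, tolerance = 1e-10)
  }
  expect_error(noise_spec(0, "x", "laser_beam"), "generator_kind")
})

test_that("tonal sweep concentrates energy along a moving ridge", {
  z <- gen_noise(noise_bank()[[1]], 1, seed = 1) # triangle sweep 500..2000 Hz
  fr <- stft_analyze(z)
  f <- (0:256) * 16000 / 512
  peaks <- f[apply(fr$lps, 1, which.max)]
  expect_true(all(peaks > 350 & peaks < 4100)) # fundamental or 2nd harmonic
  expect_gt(diff(range(peaks)), 500)           # the ridge moves
})

test_that("impulsive noise is heavier-tailed than white noise", {
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  z <- gen_noise(noise_bank()[[3]], 1, seed = 1)
  set.seed(1)
  wn <- stats::rnorm(16000) * 0.05
  expect_gt(kurt(z$samples), kurt(wn) + 3)
})

test_that("speech-shaped noise matches its design response within 3 dB", {
  z <- gen_noise(noise_bank()[[9]], 2, seed = 3)
  fr <- stft_analyze(z)
  f <- (0:256) * 16000 / 512
  mdb <- 10 * log10(colMeans(exp(fr$lps)))
  des <- 20 * log10(eanr:::ssn_design_response(pmax(f, 1)))
  sel <- f >= 100 & f <= 7000
  dev <- mdb[sel] - des[sel]
  expect_lt(max(abs(dev - mean(dev))), 3)
})

test_that("the default bank is spectrally distinct by construction", {
  specs <- vapply(noise_bank(), function(s) {
    colMeans(stft_analyze(gen_noise(s, 2, seed = 5))$lps)
  }, numeric(257))
  C <- stats::cor(specs)
  expect_lt(max(C[upper.tri(C)]), 0.95)
})

test_that("a trivial nearest-centroid classifier separates the bank", {
  bank <- noise_bank()
  centroids <- vapply(bank, function(s) {
    colMeans(stft_analyze(gen_noise(s, 1, seed = 11))$lps)
  }, numeric(257))
  hits <- 0L
  for (k in seq_along(bank)) {
    for (u in 1:5) {
      v <- colMeans(stft_analyze(gen_noise(bank[[k]], 1, seed = 100 + 13 * u + k))$lps)
      hits <- hits + (which.min(colSums((centroids - v)^2)) == k)
    }
  }
  expect_gt(hits / 60, 0.9)
})

test_that("mix_at_snr matches the closed-form gain", {
  # unit-power deterministic signals
  n <- 8000
  clean <- waveform(rep(c(1, -1), n / 2))
  noise <- waveform(rep(c(1, 1, -1, -1), n / 4))
  m0 <- mix_at_snr(clean, noise, 0)            # g = 1
  expect_equal(m0$samples, clean$samples + noise$samples, tolerance = 1e-12)
  m10 <- mix_at_snr(clean, noise, 10)          # g = 10^-0.5
  expect_equal(m10$samples, clean$samples + 10^(-0.5) * noise$samples,
               tolerance = 1e-12)
})

test_that("mixtures achieve the requested SNR within 1e-6 dB", {
  sp <- fx_speech()
  nz <- fx_noise(9L)
  for (snr in c(-10, -3, 0, 3, 10)) {
    expect_lt(abs(measured_snr(sp, mix_at_snr(sp, nz, snr)) - snr), 1e-6)
  }
})

test_that("mix_at_snr rejects degenerate inputs", {
  sp <- fx_speech()
  expect_error(mix_at_snr(sp, waveform(rep(1, 100), rate = 8000), 0), "rate")
  expect_error(mix_at_snr(waveform(rep(0, 100)), waveform(rep(1, 100)), 0), "degenerate")
  expect_error(mix_at_snr(sp, waveform(1), 0), "shorter")
})

test_that("corpus manifest covers the grid and reproduces bit-identically", {
  cfg <- corpus_config(snrs_train = c(-6, -3, 0, 3, 6), snrs_test = c(-6, -3, 0, 3, 6),
                       n_train = 4L, n_test = 2L, master_seed = 9L)
  man <- build_corpus(cfg)
  expect_equal(nrow(man), 12 * 5 * 6)
  expect_equal(anyDuplicated(man[, c("utterance_id", "class_id", "snr_db", "split")]), 0L)
  man2 <- build_corpus(cfg)
  expect_identical(as.data.frame(man), as.data.frame(man2))
  e1 <- resolve_entry(man, 17L)
  e2 <- resolve_entry(man, 17L)
  expect_identical(e1$noisy$samples, e2$noisy$samples)
  expect_lt(abs(measured_snr(e1$clean, e1$noisy) - man$snr_db[17]), 1e-6)
  expect_equal(wave_rms(e1$clean), cfg$speech_rms, tolerance = 1e-10)
})

test_that("empty corpus grids are rejected", {
  expect_error(corpus_config(classes = integer(0)), "empty")
})

test_that("noise sets for classifier training are reproducible", {
  a <- build_noise_set(n_train = 1L, n_test = 1L, duration_s = 0.3, master_seed = 5)
  b <- build_noise_set(n_train = 1L, n_test = 1L, duration_s = 0.3, master_seed = 5)
  expect_identical(lapply(a$waves, `[[`, "samples"), lapply(b$waves, `[[`, "samples"))
  expect_equal(sum(a$split == "train"), 12L)
  expect_equal(sum(a$split == "test"), 12L)
})
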