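test_that("stft config enforces its invariants", {
  expect_error(stft_config(hop = 0), "hop")
  expect_error(stft_config(frame_len = 600, fft_size = 512), "hop")
  expect_error(stft_config(log_floor = 0), "log_floor")
})

test_that("a bin-centred sine peaks at its bin in every interior frame", {
  cfg <- stft_config()
  k <- 40L # bin index (0-based): f = 40 * 16000/512 = 1250 Hz
  w <- waveform(sin(2 * pi * k / 512 * (0:16383)))
  fr <- stft_analyze(w, cfg)
  peaks <- apply(fr$lps, 1L, which.max)
  expect_true(all(peaks == k + 1L))
})

test_that("all-zero signal hits the log floor everywhere", {
  cfg <- stft_config()
  fr <- stft_analyze(waveform(rep(0, 4096)), cfg)
  expect_true(all(fr$lps == log(cfg$log_floor)))
  expect_true(all(is.finite(fr$phase)))
})

test_that("one frame obeys Parseval with symmetric-bin weighting", {
  cfg <- stft_config(frame_len = 512, hop = 512, fft_size = 512)
  set.seed(2)
  x <- stats::rnorm(512)
  fr <- stft_analyze(waveform(x), cfg)
  p <- exp(fr$lps[1, ])
  wts <- c(1, rep(2, 255), 1) # conjugate-symmetric bins counted twice
  lhs <- sum(p * wts)
  rhs <- 512 * sum((x * eanr:::stft_window(cfg))^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("lps_to_magnitude inverts the log-power transform", {
  expect_equal(lps_to_magnitude(0), 1)
  expect_equal(lps_to_magnitude(2 * log(3)), 3)
  m <- matrix(c(0.5, 2, 7, 0.01), 2)
  expect_equal(lps_to_magnitude(log(m^2)), m)
  expect_error(lps_to_magnitude(c(1, NaN)), "finite")
})

test_that("analysis/synthesis roundtrip is exact on the interior", {
  for (seed in c(7, 8)) {
    w <- gen_speech_like(0.7, seed)
    fr <- stft_analyze(w)
    rec <- stft_synthesize(fr$lps, fr$phase, fr$cfg, fr$n_samples_original)
    expect_length(rec$samples, length(w$samples))
    int <- 257:(fr$n_samples_original - 768) # skip half-frame edges + tail
    rel <- sqrt(mean((rec$samples[int] - w$samples[int])^2) / mean(w$samples[int]^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("floored (silent) spectra synthesize to near-silence", {
  cfg <- stft_config()
  w <- waveform(sin(2 * pi * 440 * (0:8191) / 16000))
  fr <- stft_analyze(w, cfg)
  silent <- stft_synthesize(matrix(log(cfg$log_floor), nrow(fr$lps), ncol(fr$lps)),
                            fr$phase, cfg, fr$n_samples_original)
  expect_lt(sum(silent$samples^2), 1e-8 * sum(w$samples^2))
})

test_that("synthesize validates shapes", {
  fr <- stft_analyze(fx_speech())
  expect_error(stft_synthesize(fr$lps[, -1], fr$phase, fr$cfg, 16000), "mismatch|bins")
  expect_error(stft_synthesize(fr$lps, fr$phase[-1, ], fr$cfg, 16000), "mismatch")
})

test_that("mfcc frames align with stft frames and respond to spectrum", {
  w <- fx_speech()
  cfg <- stft_config()
  expect_equal(nrow(mfcc_extract(w, cfg)$coeffs), nrow(stft_analyze(w, cfg)$lps))
  set.seed(3)
  wn <- waveform(stats::rnorm(8000) * 0.1)
  nb <- gen_noise(noise_bank()[[8]], 0.5, 1) # narrowband hum
  d <- sqrt(sum((colMeans(mfcc_extract(wn)$coeffs) - colMeans(mfcc_extract(nb)$coeffs))^2))
  expect_gt(d, 1)
})

test_that("amplitude scaling moves only the zeroth cepstral coefficient", {
  w <- fx_speech()
  a <- mfcc_extract(w)$coeffs
  b <- mfcc_extract(waveform(2 * w$samples, w$rate))$coeffs
  expect_gt(max(abs(b[, 1] - a[, 1])), 0.1)
  expect_lt(max(abs(b[, -1] - a[, -1])), 1e-6)
})

test_that("degenerate signals never produce non-finite features", {
  cfg <- stft_config()
  for (x in list(rep(0, 2048), rep(1, 2048), rep(c(-1, 1), 1024))) {
    w <- waveform(x)
    expect_true(all(is.finite(stft_analyze(w, cfg)$lps)))
    expect_true(all(is.finite(mfcc_extract(w, cfg)$coeffs)))
  }
  expect_error(stft_analyze(waveform(rep(0, 100)), cfg), "shorter")
  expect_error(mfcc_extract(waveform(rep(0, 100)), cfg), "shorter")
})

test_that("wav files round-trip in both formats", {
  w <- waveform(0.8 * sin(2 * pi * 300 * (0:3999) / 16000))
  p32 <- tempfile(fileext = ".wav")
  write_wav(w, p32, "float32")
  r32 <- read_wav(p32)
  expect_equal(r32$rate, 16000)
  expect_equal(r32$samples, w$samples, tolerance = 1e-7) # float32 precision
  p16 <- tempfile(fileext = ".wav")
  write_wav(w, p16, "pcm16")
  r16 <- read_wav(p16)
  expect_lt(max(abs(r16$samples - w$samples)), 1 / 32000)
  unlink(c(p16, p32))
})
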