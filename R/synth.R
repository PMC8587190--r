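# Synthetic audio: speech-like utterances, a parametric 12-class noise bank,
# exact SNR mixing and a reproducible corpus grid. Everything is a pure
# function of its configuration and seed, so corpora never need to be stored.

#' Settings for the speech-like generator
#'
#' The generator produces harmonic signals with a piecewise-varying
#' fundamental, formant-like spectral resonances and syllable-rate amplitude
#' modulation. It emulates the gross acoustic structure of read speech (the
#' structure STOI and the denoiser respond to), not any particular language.
#'
#' @param rate Sampling rate in Hz.
#' @param f0_range Fundamental-frequency range in Hz; the contour is a
#'   piecewise-linear random walk inside this range.
#' @param formant_ranges List of (lo, hi) Hz ranges; one resonance centre is
#'   drawn per range and held for the utterance.
#' @param formant_bw Gaussian bandwidth (Hz) of each resonance bump.
#' @param syllable_range Syllabic amplitude-modulation rate range in Hz.
#' @param tilt_ref Spectral-tilt reference frequency in Hz (energy falls off
#'   above it, as in voiced speech).
#' @param noise_floor Relative level of the aspiration-noise floor.
#' @return A list of class `eanr_speech_cfg`.
#' @export
speech_cfg <- function(rate = 16000,
                       f0_range = c(100, 250),
                       formant_ranges = list(c(300, 900), c(1000, 2200), c(2300, 3200)),
                       formant_bw = c(110, 160, 220),
                       syllable_range = c(2, 6),
                       tilt_ref = 500,
                       noise_floor = 0.015) {
  structure(list(rate = rate, f0_range = f0_range,
                 formant_ranges = formant_ranges, formant_bw = formant_bw,
                 syllable_range = syllable_range, tilt_ref = tilt_ref,
                 noise_floor = noise_floor),
            class = "eanr_speech_cfg")
}

#' Generate a speech-like utterance
#'
#' Additive harmonic synthesis: a seeded piecewise-linear fundamental contour,
#' per-harmonic amplitudes drawn from a formant-bump spectral envelope with a
#' low-pass tilt, syllable-rate amplitude modulation and a weak aspiration
#' noise floor. Identical `(duration_s, seed, cfg)` give bit-identical output.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param seed Integer seed.
#' @param cfg A [speech_cfg()].
#' @return An `eanr_wave` with peak amplitude <= 1.
#' @examples
#' w <- gen_speech_like(0.5, seed = 7)
#' @export
gen_speech_like <- function(duration_s, seed, cfg = speech_cfg()) {
  check_scalar_num(duration_s, "duration_s", lower = 1e-9)
  rate <- cfg$rate
  n <- max(1L, as.integer(round(duration_s * rate)))
  tt <- (seq_len(n) - 1) / rate
  with_seed(seed, {
    # fundamental contour: ~5 targets per second, linearly interpolated
    n_seg <- max(2L, ceiling(duration_s * 5))
    targets <- stats::runif(n_seg + 1L, cfg$f0_range[1], cfg$f0_range[2])
    f0 <- stats::approx(seq(0, duration_s, length.out = n_seg + 1L), targets,
                        xout = tt, rule = 2)$y
    phase <- 2 * pi * cumsum(f0) / rate

    fc <- vapply(cfg$formant_ranges, function(r) stats::runif(1, r[1], r[2]), 0)
    bw <- cfg$formant_bw
    envf <- function(f) {
      e <- 0.03
      for (j in seq_along(fc)) e <- e + exp(-0.5 * ((f - fc[j]) / bw[j])^2)
      e / (1 + (f / cfg$tilt_ref)^2)^0.5
    }

    nyq <- rate / 2 - 200
    n_harm <- floor(nyq / min(f0))
    sig <- numeric(n)
    for (k in seq_len(n_harm)) {
      fk <- k * f0
      live <- fk < nyq
      if (!any(live)) break
      ak <- envf(fk) * live
      if (max(ak) < 1e-4) next
      sig <- sig + ak * sin(k * phase + stats::runif(1, 0, 2 * pi))
    }

    f_syl <- stats::runif(1, cfg$syllable_range[1], cfg$syllable_range[2])
    ph_syl <- stats::runif(1, 0, 2 * pi)
    env <- (0.1 + 0.9 * (0.5 - 0.5 * cos(2 * pi * f_syl * tt + ph_syl)))^2
    sig <- sig * env
    sig <- sig + cfg$noise_floor * stats::rnorm(n) * env * stats::sd(sig)
    waveform(0.95 * sig / max(abs(sig)), rate)
  })
}

# ---------------------------------------------------------------------------
# Noise bank
# ---------------------------------------------------------------------------

noise_kinds <- c("tonal_sweep", "impulsive", "babble_like", "speech_shaped",
                 "narrowband_hum", "broadband", "mixture")

#' Describe one synthetic noise class
#'
#' @param class_id Integer id, unique within a bank (0-based, matching the
#'   classifier's label space).
#' @param name Human-readable label.
#' @param generator_kind One of `tonal_sweep`, `impulsive`, `babble_like`,
#'   `speech_shaped`, `narrowband_hum`, `broadband`, `mixture`.
#' @param params Generator-specific settings (see the default bank source for
#'   the recognised fields of each kind).
#' @return A list of class `eanr_noise_spec`.
#' @export
noise_spec <- function(class_id, name, generator_kind, params = list()) {
  if (!generator_kind %in% noise_kinds) {
    stop_invalid("unknown generator_kind '%s'", generator_kind)
  }
  structure(list(class_id = as.integer(class_id), name = name,
                 generator_kind = generator_kind, params = params),
            class = "eanr_noise_spec")
}

#' The default 12-class noise bank
#'
#' Twelve spectrally distinct noise generators emulating the qualitative
#' categories of common assistive-listening backgrounds: sirens and alarms
#' (tonal sweeps), jackhammer and squeaking-toy impulses, two-talker and
#' crowd babble, fan hum, speech-shaped noise, transit rumble, and two
#' composite mixtures. Class ids are 0..11.
#'
#' @param target_rms RMS amplitude every generated noise is normalized to.
#' @return A list of [noise_spec()] objects.
#' @export
noise_bank <- function(target_rms = 0.05) {
  mk <- function(id, name, kind, ...) {
    noise_spec(id, name, kind, params = c(list(target_rms = target_rms), list(...)))
  }
  list(
    mk(0L, "siren",        "tonal_sweep", f_lo = 500, f_hi = 2000, period_s = 0.8,
       mode = "triangle", harmonics = 2L),
    mk(1L, "alarm",        "tonal_sweep", f_lo = 900, f_hi = 1700, period_s = 0.25,
       mode = "alternate", harmonics = 1L),
    mk(2L, "jackhammer",   "impulsive", burst_rate_hz = 9, decay_s = 0.012,
       band = c(250, 3500), tone = FALSE),
    mk(3L, "toy_squeak",   "impulsive", burst_rate_hz = 2.5, decay_s = 0.06,
       band = c(1200, 4200), tone = TRUE, tone_range = c(1600, 3200)),
    mk(4L, "babble2_low",  "babble_like", n_talkers = 2L,
       f0_range = c(85, 150), formant_scale = 0.85, floor_db = -40),
    mk(5L, "babble2_high", "babble_like", n_talkers = 2L,
       f0_range = c(170, 300), formant_scale = 1.3, floor_db = -40),
    mk(6L, "cafeteria",    "babble_like", n_talkers = 6L,
       f0_range = c(100, 250), formant_scale = 1.0, floor_db = -10,
       floor_kind = "white"),
    mk(7L, "fan_hum",      "narrowband_hum", f0 = 120, n_harm = 24L,
       noise_db = -18, lp_hz = 300, floor_db = -38),
    mk(8L, "ssn",          "speech_shaped"),
    mk(9L, "rumble",       "broadband", cut_hz = 280, order = 8, floor_db = -46),
    mk(10L, "siren_crowd", "mixture", components = c(0L, 6L), gains_db = c(6, -6)),
    mk(11L, "impact_hiss", "mixture", components = c(2L), hiss_hp_hz = 3000,
       gains_db = c(0, -4))
  )
}

# FFT-domain shaping of seeded white noise by a magnitude response |H|(f).
shaped_noise <- function(n, rate, hfun) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * rate / n
  x <- Re(stats::fft(W * hfun(f), inverse = TRUE)) / n
  x
}

# Design magnitude response of the speech-shaped class: flat through the first
# formant region then -6 dB/octave, with a steep roll-on below 100 Hz.
# Exposed internally so tests can compare the realized spectrum to the design.
ssn_design_response <- function(f) {
  (f^2 / (f^2 + 60^2)) / sqrt(1 + (f / 500)^2)
}

#' Generate one noise realization
#'
#' Deterministic given `(spec, duration_s, seed)`; the output is normalized to
#' the spec's `target_rms` (default 0.05).
#'
#' @param spec A [noise_spec()], typically from [noise_bank()].
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @param bank The bank the spec belongs to (needed only by `mixture` specs to
#'   resolve their component classes).
#' @return An `eanr_wave`.
#' @export
gen_noise <- function(spec, duration_s, seed, bank = noise_bank()) {
  stopifnot(inherits(spec, "eanr_noise_spec"))
  check_scalar_num(duration_s, "duration_s", lower = 1e-9)
  rate <- 16000
  n <- max(1L, as.integer(round(duration_s * rate)))
  tt <- (seq_len(n) - 1) / rate
  p <- spec$params
  x <- with_seed(derive_seed(seed, spec$class_id, 101), {
    switch(spec$generator_kind,
      tonal_sweep = {
        ph_t <- tt / p$period_s
        if (identical(p$mode, "alternate")) {
          f <- ifelse((ph_t %% 1) < 0.5, p$f_lo, p$f_hi)
        } else { # triangle sweep
          tri <- 2 * abs(ph_t %% 1 - 0.5)
          f <- p$f_lo + (p$f_hi - p$f_lo) * (1 - tri)
        }
        phase <- 2 * pi * cumsum(f) / rate
        s <- sin(phase)
        for (k in seq_len(p$harmonics %||% 1L)[-1]) s <- s + 0.4^(k - 1) * sin(k * phase)
        s + 0.01 * stats::rnorm(n)
      },
      impulsive = {
        # jittered burst train convolved with a damped band-limited kernel
        period <- rate / p$burst_rate_hz
        base_onsets <- seq(1, n, by = period)
        onsets <- round(base_onsets + stats::runif(length(base_onsets), 0, 0.3 * period))
        onsets <- onsets[onsets >= 1 & onsets <= n]
        s <- numeric(n)
        klen <- min(n, as.integer(6 * p$decay_s * rate))
        kt <- (seq_len(klen) - 1) / rate
        for (o in onsets) {
          if (isTRUE(p$tone)) {
            ftone <- stats::runif(1, p$tone_range[1], p$tone_range[2])
            burst <- sin(2 * pi * ftone * kt * (1 + 0.15 * kt / max(kt))) * exp(-kt / p$decay_s)
          } else {
            bn <- stats::rnorm(klen)
            burst <- bn * exp(-kt / p$decay_s)
          }
          idx <- o:min(n, o + klen - 1L)
          s[idx] <- s[idx] + burst[seq_along(idx)]
        }
        if (!isTRUE(p$tone)) {
          # band-limit the broadband bursts
          S <- stats::fft(s)
          f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * rate / n
          h <- as.numeric(f >= p$band[1] & f <= p$band[2])
          s <- Re(stats::fft(S * h, inverse = TRUE)) / n
        }
        s
      },
      babble_like = {
        cfg <- speech_cfg(rate = rate,
                          f0_range = p$f0_range,
                          formant_ranges = lapply(speech_cfg()$formant_ranges,
                                                  function(r) r * p$formant_scale))
        s <- numeric(n)
        for (j in seq_len(p$n_talkers)) {
          s <- s + gen_speech_like(duration_s, derive_seed(seed, spec$class_id, j), cfg)$samples[1:n]
        }
        fl <- 10^(p$floor_db / 20)
        sn <- if (identical(p$floor_kind, "white")) stats::rnorm(n)
              else shaped_noise(n, rate, ssn_design_response)
        s / stats::sd(s) + fl * sn / stats::sd(sn)
      },
      speech_shaped = shaped_noise(n, rate, ssn_design_response),
      narrowband_hum = {
        drift <- 1 + 0.004 * sin(2 * pi * 0.7 * tt)
        phase <- 2 * pi * p$f0 * cumsum(drift) / rate
        s <- numeric(n)
        for (k in seq_len(p$n_harm)) s <- s + (0.7^(k - 1)) * sin(k * phase)
        lp <- shaped_noise(n, rate, function(f) 1 / (1 + (f / p$lp_hz)^4))
        wf <- stats::rnorm(n)
        s / stats::sd(s) + 10^(p$noise_db / 20) * lp / stats::sd(lp) +
          10^((p$floor_db %||% -60) / 20) * wf
      },
      broadband = shaped_noise(n, rate, function(f) {
        1 / (1 + (f / p$cut_hz)^p$order) + 10^(p$floor_db / 20)
      }),
      mixture = {
        s <- numeric(n)
        gains <- 10^(p$gains_db / 20)
        for (j in seq_along(p$components)) {
          comp <- bank[[p$components[j] + 1L]]
          s <- s + gains[j] * gen_noise(comp, duration_s, derive_seed(seed, 7, j), bank)$samples[1:n]
        }
        if (!is.null(p$hiss_hp_hz)) {
          hiss <- shaped_noise(n, rate, function(f) as.numeric(f >= p$hiss_hp_hz))
          s <- s + gains[length(gains)] * 0.05 * hiss / stats::sd(hiss)
        }
        s
      },
      stop_invalid("unknown generator_kind '%s'", spec$generator_kind)
    )
  })
  target <- p$target_rms %||% 0.05
  waveform(x * (target / sqrt(mean(x^2))), rate)
}

# ---------------------------------------------------------------------------
# SNR mixing
# ---------------------------------------------------------------------------

#' Mix clean speech with noise at an exact SNR
#'
#' The noise is truncated to the clean signal's length and scaled by
#' `g = sqrt(P_clean / (P_noise * 10^(snr_db / 10)))`, so the power ratio of
#' the two addends equals the requested SNR to within floating-point
#' round-off (well inside 1e-6 dB).
#'
#' @param clean,noise `eanr_wave` objects with equal rates; the noise must be
#'   at least as long as the clean signal.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return The noisy mixture as an `eanr_wave`.
#' @examples
#' sp <- gen_speech_like(0.5, 1)
#' nz <- gen_noise(noise_bank()[[9]], 0.5, 1)
#' noisy <- mix_at_snr(sp, nz, 0)
#' measured_snr(sp, noisy)
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  stopifnot(is_wave(clean), is_wave(noise))
  check_scalar_num(snr_db, "snr_db")
  if (clean$rate != noise$rate) stop_invalid("rate mismatch: %g vs %g Hz", clean$rate, noise$rate)
  n <- length(clean$samples)
  if (length(noise$samples) < n) stop_invalid("noise shorter than clean signal")
  nz <- noise$samples[seq_len(n)]
  pc <- mean(clean$samples^2)
  pn <- mean(nz^2)
  if (pc <= 0 || pn <= 0) stop_invalid("degenerate input: zero-power clean or noise")
  g <- sqrt(pc / (pn * 10^(snr_db / 10)))
  waveform(clean$samples + g * nz, clean$rate)
}

#' Measure the realized SNR of a mixture
#'
#' Recovers the scaled-noise addend as `noisy - clean` and returns
#' `10 * log10(P_clean / P_noise)` in dB.
#'
#' @param clean The clean `eanr_wave` used in the mixture.
#' @param noisy The mixture (same length and rate).
#' @return SNR in dB.
#' @export
measured_snr <- function(clean, noisy) {
  stopifnot(is_wave(clean), is_wave(noisy))
  if (length(clean$samples) != length(noisy$samples)) stop_invalid("length mismatch")
  res <- noisy$samples - clean$samples
  10 * log10(mean(clean$samples^2) / mean(res^2))
}

# ---------------------------------------------------------------------------
# Corpus grid
# ---------------------------------------------------------------------------

#' Configuration for a synthetic noisy-speech corpus
#'
#' Defines the (noise class x SNR x split) grid. Defaults follow the training
#' and test SNR lists used for denoiser development: train
#' \{-10, -7, -4, -1, 1, 4, 7, 10\} dB, test \{-6, -3, 0, 3, 6\} dB. Clean
#' speech is RMS-normalized to `speech_rms` before mixing.
#'
#' @param bank Noise bank (list of [noise_spec()]).
#' @param classes Integer class ids to include (default: all classes in bank).
#' @param snrs_train,snrs_test SNR grids (dB) for the two splits.
#' @param n_train,n_test Utterances per (class, SNR) cell in each split.
#' @param duration_s Utterance duration in seconds.
#' @param speech_rms Pre-mixing clean-speech RMS.
#' @param master_seed Master seed; every entry's seeds derive from it.
#' @param speech Optional [speech_cfg()].
#' @return A list of class `eanr_corpus_cfg`.
#' @export
corpus_config <- function(bank = noise_bank(),
                          classes = NULL,
                          snrs_train = c(-10, -7, -4, -1, 1, 4, 7, 10),
                          snrs_test = c(-6, -3, 0, 3, 6),
                          n_train = 4L, n_test = 2L,
                          duration_s = 1,
                          speech_rms = 0.05,
                          master_seed = 1L,
                          speech = speech_cfg()) {
  classes <- classes %||% vapply(bank, function(s) s$class_id, 0L)
  if (length(classes) < 1L || (length(snrs_train) + length(snrs_test)) < 1L) {
    stop_invalid("corpus grid is empty")
  }
  structure(list(bank = bank, classes = as.integer(classes),
                 snrs_train = snrs_train, snrs_test = snrs_test,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 duration_s = duration_s, speech_rms = speech_rms,
                 master_seed = as.integer(master_seed), speech = speech),
            class = "eanr_corpus_cfg")
}

#' Build a corpus manifest
#'
#' Expands the full (class x SNR x utterance x split) grid into a manifest
#' data frame with per-entry seeds derived from the master seed. The manifest
#' is the corpus: [resolve_entry()] regenerates any entry's (clean, noisy)
#' pair bit-identically.
#'
#' @param cfg A [corpus_config()].
#' @return A data frame of class `eanr_manifest` with columns `utterance_id`,
#'   `class_id`, `snr_db`, `split`, `seed_speech`, `seed_noise`, and the
#'   config stored as attribute `cfg`.
#' @export
build_corpus <- function(cfg = corpus_config()) {
  stopifnot(inherits(cfg, "eanr_corpus_cfg"))
  rows <- list()
  for (split in c("train", "test")) {
    snrs <- if (split == "train") cfg$snrs_train else cfg$snrs_test
    n_utt <- if (split == "train") cfg$n_train else cfg$n_test
    if (n_utt < 1L || length(snrs) < 1L) next
    for (cls in cfg$classes) {
      for (snr in snrs) {
        for (u in seq_len(n_utt)) {
          tag <- if (split == "train") 1L else 2L
          rows[[length(rows) + 1L]] <- data.frame(
            utterance_id = sprintf("c%02d_%s_snr%+03d_u%02d", cls, split, round(snr), u),
            class_id = cls, snr_db = snr, split = split,
            seed_speech = derive_seed(cfg$master_seed, tag, cls, round(snr * 10), u, 1),
            seed_noise = derive_seed(cfg$master_seed, tag, cls, round(snr * 10), u, 2),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  man <- do.call(rbind, rows)
  if (anyDuplicated(man$utterance_id)) stop("internal: duplicate manifest ids")
  attr(man, "cfg") <- cfg
  class(man) <- c("eanr_manifest", class(man))
  man
}

#' Resolve one manifest entry to audio
#'
#' Regenerates the clean utterance (RMS-normalized) and the noisy mixture for
#' row `i` of a manifest. Pure and deterministic: resolving twice yields
#' bit-identical waveforms.
#'
#' @param manifest An `eanr_manifest` from [build_corpus()].
#' @param i Row index.
#' @return `list(clean, noisy, class_id, snr_db, split)`.
#' @export
resolve_entry <- function(manifest, i) {
  stopifnot(inherits(manifest, "eanr_manifest"))
  cfg <- attr(manifest, "cfg")
  e <- manifest[i, ]
  clean <- wave_normalize_rms(
    gen_speech_like(cfg$duration_s, e$seed_speech, cfg$speech),
    cfg$speech_rms
  )
  spec <- NULL
  for (s in cfg$bank) if (s$class_id == e$class_id) spec <- s
  if (is.null(spec)) stop_invalid("class %d not in bank", e$class_id)
  noise <- gen_noise(spec, cfg$duration_s, e$seed_noise, bank = cfg$bank)
  noisy <- mix_at_snr(clean, noise, e$snr_db)
  list(clean = clean, noisy = noisy, class_id = e$class_id,
       snr_db = e$snr_db, split = e$split)
}

#' Generate labelled noise-only clips
#'
#' Training/evaluation material for the noise classifier: `n_train + n_test`
#' independent realizations of each class in the bank, with seeds derived from
#' the master seed so the set is reproducible.
#'
#' @param bank Noise bank.
#' @param n_train,n_test Clips per class in each split.
#' @param duration_s Clip duration in seconds.
#' @param master_seed Master seed.
#' @return `list(waves, class_id, split)`: a list of `eanr_wave` plus parallel
#'   label and split vectors.
#' @export
build_noise_set <- function(bank = noise_bank(), n_train = 20L, n_test = 10L,
                            duration_s = 1, master_seed = 1L) {
  waves <- list(); cls <- integer(); split <- character()
  for (s in bank) {
    for (u in seq_len(n_train + n_test)) {
      sp <- if (u <= n_train) "train" else "test"
      waves[[length(waves) + 1L]] <-
        gen_noise(s, duration_s, derive_seed(master_seed, 3L, s$class_id, u), bank = bank)
      cls <- c(cls, s$class_id)
      split <- c(split, sp)
    }
  }
  list(waves = waves, class_id = cls, split = split)
}
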