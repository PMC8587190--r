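# Objective evaluation: short-time objective intelligibility (STOI), word
# correct rate, a pluggable PESQ backend, layer-separability profiling and a
# condition-table scorer.

# --- classic STOI ----------------------------------------------------------
# Short-time objective intelligibility (Taal, Hendriks, Heusdens & Jensen,
# 2011): resample to 10 kHz, drop silent frames, analyse in 15 one-third
# octave bands (centres 150 Hz * 2^(k/3)), and average, over 384 ms segments
# and bands, the correlation between clean and normalized/clipped degraded
# band envelopes.

STOI_FS <- 10000L
STOI_FRAME <- 256L
STOI_NFFT <- 512L
STOI_NBANDS <- 15L
STOI_MINFREQ <- 150
STOI_SEG <- 30L      # 30 frames of 128-sample hop = 384 ms
STOI_BETA <- -15     # lower signal-to-distortion bound (dB) for clipping
STOI_DYN <- 40       # silent-frame dynamic range (dB)

# Fourier-domain resampling (length-preserving in duration). Adequate here:
# signals are short, offline and band-limited well below the target Nyquist.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  kh <- floor(min(n, n_out) / 2)
  Y[1:(kh + 1L)] <- X[1:(kh + 1L)]
  if (kh >= 1L) Y[(n_out - kh + 1L):n_out] <- X[(n - kh + 1L):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

hann_sym <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

frame_signal <- function(x, frame, hop) {
  nf <- 1L + (length(x) - frame) %/% hop
  idx <- outer(seq_len(frame), (seq_len(nf) - 1L) * hop, "+")
  matrix(x[idx], frame, nf)
}

# Drop frames whose clean-signal energy is more than STOI_DYN dB below the
# loudest frame; both signals are rebuilt by overlap-adding the kept windowed
# frames (the reference procedure).
stoi_remove_silent <- function(x, y) {
  frame <- STOI_FRAME; hop <- frame %/% 2L
  w <- hann_sym(frame)
  fx <- frame_signal(x, frame, hop) * w
  fy <- frame_signal(y, frame, hop) * w
  en <- 20 * log10(sqrt(colSums(fx^2)) + 1e-300)
  keep <- which(en > max(en) - STOI_DYN)
  if (length(keep) == 0L) stop_invalid("signal is entirely silent")
  n_out <- (length(keep) - 1L) * hop + frame
  xs <- numeric(n_out); ys <- numeric(n_out)
  for (j in seq_along(keep)) {
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + frame)
    xs[idx] <- xs[idx] + fx[, keep[j]]
    ys[idx] <- ys[idx] + fy[, keep[j]]
  }
  list(x = xs, y = ys)
}

# One-third octave band matrix (bands x bins): each band collects FFT bins
# between its lower and upper edge, edges snapped to the nearest bin centre.
stoi_band_matrix <- function() {
  f <- (0:(STOI_NFFT / 2)) * STOI_FS / STOI_NFFT
  cf <- STOI_MINFREQ * 2^((seq_len(STOI_NBANDS) - 1) / 3)
  A <- matrix(0, STOI_NBANDS, length(f))
  for (i in seq_len(STOI_NBANDS)) {
    kl <- which.min((f - cf[i] * 2^(-1 / 6))^2)
    kr <- which.min((f - cf[i] * 2^(1 / 6))^2)
    if (kr > kl) A[i, kl:(kr - 1L)] <- 1
  }
  A
}

stoi_band_env <- function(x) {
  frame <- STOI_FRAME; hop <- frame %/% 2L
  fr <- frame_signal(x, frame, hop) * hann_sym(frame)
  fr <- rbind(fr, matrix(0, STOI_NFFT - frame, ncol(fr)))
  S <- stats::mvfft(fr)[1:(STOI_NFFT / 2 + 1), , drop = FALSE]
  sqrt(stoi_band_matrix() %*% Mod(S)^2) # bands x frames
}

#' Short-time objective intelligibility (STOI)
#'
#' Classic STOI: the mean, over 15 one-third octave bands and 384 ms
#' segments, of the correlation between the clean and the
#' normalized-and-clipped degraded band envelopes, computed at 10 kHz after
#' removal of silent frames. Scores lie in about \[0, 1\] for speech, higher
#' meaning more intelligible; the self-comparison `eval_stoi(x, x)` is 1.
#'
#' @param clean,processed `eanr_wave` objects at the same rate; the longer is
#'   trimmed to the shorter. About 0.4 s of non-silent audio is the practical
#'   minimum for the segment analysis.
#' @return A single STOI value.
#' @examples
#' sp <- gen_speech_like(1, 1)
#' nz <- gen_noise(noise_bank()[[9]], 1, 1)
#' eval_stoi(sp, mix_at_snr(sp, nz, 0))
#' @export
eval_stoi <- function(clean, processed) {
  stopifnot(is_wave(clean), is_wave(processed))
  if (clean$rate != processed$rate) stop_invalid("rate mismatch")
  n <- min(length(clean$samples), length(processed$samples))
  if (n / clean$rate < 0.25) stop_invalid("signals too short for STOI (< 0.25 s)")
  x <- clean$samples[seq_len(n)]
  y <- processed$samples[seq_len(n)]
  if (clean$rate != STOI_FS) {
    m <- as.integer(round(n * STOI_FS / clean$rate))
    x <- resample_fft(x, m)
    y <- resample_fft(y, m)
  }
  s <- stoi_remove_silent(x, y)
  Xb <- stoi_band_env(s$x)
  Yb <- stoi_band_env(s$y)
  M <- ncol(Xb)
  if (M < STOI_SEG) stop_invalid("too few frames after silence removal (%d < %d)", M, STOI_SEG)
  clip_gain <- 1 + 10^(-STOI_BETA / 20)
  total <- 0; cnt <- 0L
  for (m in STOI_SEG:M) {
    cols <- (m - STOI_SEG + 1L):m
    Xs <- Xb[, cols, drop = FALSE]
    Ys <- Yb[, cols, drop = FALSE]
    alpha <- sqrt(rowSums(Xs^2) / pmax(rowSums(Ys^2), 1e-300))
    Yn <- pmin(Ys * alpha, Xs * clip_gain)
    xm <- Xs - rowMeans(Xs)
    ym <- Yn - rowMeans(Yn)
    dd <- rowSums(xm * ym) / pmax(sqrt(rowSums(xm^2) * rowSums(ym^2)), 1e-300)
    total <- total + sum(dd)
    cnt <- cnt + length(dd)
  }
  total / cnt
}

# --- PESQ ------------------------------------------------------------------

#' Perceptual evaluation of speech quality (pluggable backend)
#'
#' PESQ (ITU-T P.862) is consumed from an external implementation, never
#' re-derived here. Register one with
#' `options(eanr.pesq_backend = function(clean, processed, rate) ...)`
#' returning a MOS-LQO value; without a registered backend this function
#' signals an error after validating its contract (equal rates, rate 8 or
#' 16 kHz).
#'
#' @param clean,processed `eanr_wave` objects at the same rate.
#' @return MOS-LQO value from the registered backend.
#' @export
eval_pesq <- function(clean, processed) {
  stopifnot(is_wave(clean), is_wave(processed))
  if (clean$rate != processed$rate) stop_invalid("rate mismatch")
  if (!clean$rate %in% c(8000, 16000)) {
    stop_invalid("PESQ supports 8 or 16 kHz input, got %g Hz", clean$rate)
  }
  backend <- getOption("eanr.pesq_backend", NULL)
  if (is.null(backend)) {
    stop("no PESQ backend registered; set options(eanr.pesq_backend = ...) to an ITU P.862 implementation",
         call. = FALSE)
  }
  backend(clean, processed, clean$rate)
}

# --- word correct rate -----------------------------------------------------

#' Word correct rate
#'
#' The percentage of words a listener repeats correctly:
#' `100 * n_correct / n_total`.
#'
#' @param n_correct,n_total Non-negative counts with
#'   `0 <= n_correct <= n_total`, `n_total > 0`.
#' @return WCR in percent.
#' @examples
#' wcr(41, 1000) # 4.1
#' @export
wcr <- function(n_correct, n_total) {
  check_scalar_num(n_correct, "n_correct", lower = 0)
  check_scalar_num(n_total, "n_total", lower = 1)
  if (n_correct > n_total) stop_invalid("n_correct exceeds n_total")
  100 * n_correct / n_total
}

# --- layer separability ----------------------------------------------------

#' Clean/noisy separability of each denoiser layer
#'
#' Feeds clean-speech frames and noisy frames through the network, collects
#' every layer's activations, and scores how well each layer separates the
#' two populations with a two-class silhouette coefficient (Euclidean
#' distance on raw activations; any 2-D embedding is cosmetic and never used
#' for the score). In a trained five-layer denoiser the profile peaks at an
#' interior layer — the representations diverge where the network
#' distinguishes noise from speech and re-converge as it reconstructs clean
#' speech — which is the argument for substituting an interior layer in
#' knowledge transfer.
#'
#' @param model A trained `eanr_ddae`.
#' @param noisy_lps,clean_lps Non-empty LPS matrices (or [stft_analyze()]
#'   results).
#' @param sample_cap Frames kept per population (seeded subsample).
#' @param seed Subsampling seed.
#' @param embedding If `TRUE`, attach 2-D classical MDS coordinates of the
#'   final subsample at each layer (plotting aid only).
#' @return A data frame of class `eanr_separability`: `layer`, `silhouette`
#'   (in \[-1, 1\]).
#' @export
layer_separability <- function(model, noisy_lps, clean_lps, sample_cap = 2000L,
                               seed = 1L, embedding = FALSE) {
  stopifnot(inherits(model, "eanr_ddae"))
  Xn <- as_lps_matrix(noisy_lps)
  Xc <- as_lps_matrix(clean_lps)
  if (nrow(Xn) == 0L || nrow(Xc) == 0L) stop_invalid("empty input")
  hn <- mlp_forward(model, ddae_normalize(model, Xn), return_hidden = TRUE)$hidden
  hc <- mlp_forward(model, ddae_normalize(model, Xc), return_hidden = TRUE)$hidden
  L <- length(hn)
  sel_n <- with_seed(derive_seed(seed, 1), sample.int(nrow(Xn), min(sample_cap, nrow(Xn))))
  sel_c <- with_seed(derive_seed(seed, 2), sample.int(nrow(Xc), min(sample_cap, nrow(Xc))))
  scores <- numeric(L)
  embeds <- if (embedding) vector("list", L)
  for (l in seq_len(L)) {
    A <- rbind(hc[[l]][sel_c, , drop = FALSE], hn[[l]][sel_n, , drop = FALSE])
    lab <- rep(1:2, c(length(sel_c), length(sel_n)))
    D <- stats::dist(A)
    sil <- cluster::silhouette(lab, D)
    scores[l] <- mean(sil[, "sil_width"])
    if (embedding) embeds[[l]] <- stats::cmdscale(D, k = 2)
  }
  out <- data.frame(layer = seq_len(L), silhouette = scores)
  if (embedding) attr(out, "embedding") <- embeds
  class(out) <- c("eanr_separability", class(out))
  out
}

# --- condition tables ------------------------------------------------------

#' Score processing methods over every corpus condition
#'
#' Applies each method to every test-split mixture and emits exactly one row
#' per (method, noise class, SNR) cell — no silent drops — with mean STOI and
#' mean PESQ (NA without a registered backend).
#'
#' @param manifest An `eanr_manifest`.
#' @param methods Named list of functions `function(noisy_wave) -> eanr_wave`
#'   (e.g. `list(noisy = identity, system = \(w) enhance_utterance(sys, w)$enhanced)`).
#' @param split Manifest split to score.
#' @return Data frame `method, class_id, snr_db, mean_stoi, mean_pesq, n`.
#' @export
score_conditions <- function(manifest, methods, split = "test") {
  stopifnot(inherits(manifest, "eanr_manifest"), is.list(methods),
            !is.null(names(methods)), all(nzchar(names(methods))))
  idx <- which(manifest$split == split)
  if (length(idx) == 0L) stop_invalid("no '%s' entries in manifest", split)
  pesq_fun <- getOption("eanr.pesq_backend", NULL)
  resolved <- lapply(idx, function(i) resolve_entry(manifest, i))
  grid <- unique(manifest[idx, c("class_id", "snr_db")])
  rows <- list()
  for (mname in names(methods)) {
    f <- methods[[mname]]
    for (g in seq_len(nrow(grid))) {
      sel <- Filter(function(e) e$class_id == grid$class_id[g] && e$snr_db == grid$snr_db[g],
                    resolved)
      st <- vapply(sel, function(e) eval_stoi(e$clean, f(e$noisy)), 0)
      pq <- if (!is.null(pesq_fun)) {
        vapply(sel, function(e) eval_pesq(e$clean, f(e$noisy)), 0)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        method = mname, class_id = grid$class_id[g], snr_db = grid$snr_db[g],
        mean_stoi = mean(st), mean_pesq = mean(pq), n = length(sel))
    }
  }
  do.call(rbind, rows)
}
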