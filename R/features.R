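# Short-time Fourier analysis/synthesis, log-power-spectrum (LPS) and MFCC
# extraction. The denoiser works on LPS frames; the enhanced waveform is
# reconstructed from enhanced LPS plus the unmodified noisy phase.

#' STFT configuration
#'
#' Defaults are standard 16 kHz speech-enhancement practice: 512-sample
#' (32 ms) periodic Hann frames, 256-sample hop, 512-point FFT (257 bins).
#' `log_floor` is the power floor applied before taking logs; it is the sole
#' guard against `-Inf` in LPS features.
#'
#' @param frame_len Frame length in samples.
#' @param hop Hop size in samples (`0 < hop <= frame_len`).
#' @param fft_size FFT length (`>= frame_len`).
#' @param window Window name; `"hann"` (periodic) is supported.
#' @param log_floor Small positive power floor.
#' @return A list of class `eanr_stft_cfg`.
#' @export
stft_config <- function(frame_len = 512L, hop = 256L, fft_size = 512L,
                        window = "hann", log_floor = 1e-12) {
  frame_len <- as.integer(frame_len); hop <- as.integer(hop)
  fft_size <- as.integer(fft_size)
  if (!(hop > 0L && hop <= frame_len && frame_len <= fft_size)) {
    stop_invalid("need 0 < hop <= frame_len <= fft_size")
  }
  if (!identical(window, "hann")) stop_invalid("only the 'hann' window is supported")
  check_scalar_num(log_floor, "log_floor", lower = .Machine$double.xmin)
  structure(list(frame_len = frame_len, hop = hop, fft_size = fft_size,
                 window = window, log_floor = log_floor),
            class = "eanr_stft_cfg")
}

stft_window <- function(cfg) {
  n <- cfg$frame_len
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n) # periodic Hann
}

# frame start indices and count for a signal of length n
stft_n_frames <- function(n, cfg) {
  if (n < cfg$frame_len) stop_invalid("signal shorter than one frame (%d < %d)", n, cfg$frame_len)
  1L + (n - cfg$frame_len) %/% cfg$hop
}

#' STFT analysis to log-power spectrum and phase
#'
#' Frames the signal (no padding; trailing samples short of a full frame are
#' dropped from the frame grid but remembered for exact-length inversion),
#' applies a periodic Hann window and an FFT, and returns the floored
#' log-power spectrum `log(max(|X|^2, log_floor))` together with the phase.
#'
#' @param wave An `eanr_wave` at least one frame long.
#' @param cfg An [stft_config()].
#' @return An object of class `eanr_frames`: `lps` and `phase` matrices
#'   (frames x bins, bins = `fft_size/2 + 1`), plus `cfg`, `rate` and
#'   `n_samples_original`.
#' @export
stft_analyze <- function(wave, cfg = stft_config()) {
  stopifnot(is_wave(wave))
  x <- wave$samples
  nf <- stft_n_frames(length(x), cfg)
  win <- stft_window(cfg)
  starts <- (seq_len(nf) - 1L) * cfg$hop
  idx <- outer(seq_len(cfg$frame_len), starts, "+")
  fr <- matrix(x[idx], cfg$frame_len, nf) * win
  if (cfg$fft_size > cfg$frame_len) {
    fr <- rbind(fr, matrix(0, cfg$fft_size - cfg$frame_len, nf))
  }
  S <- stats::mvfft(fr)
  bins <- cfg$fft_size %/% 2L + 1L
  S <- S[seq_len(bins), , drop = FALSE]
  structure(list(lps = t(log(pmax(Mod(S)^2, cfg$log_floor))),
                 phase = t(Arg(S)),
                 cfg = cfg, rate = wave$rate,
                 n_samples_original = length(x)),
            class = "eanr_frames")
}

#' @export
print.eanr_frames <- function(x, ...) {
  cat(sprintf("<eanr_frames> %d frames x %d bins (frame %d, hop %d, fft %d) from %d samples\n",
              nrow(x$lps), ncol(x$lps), x$cfg$frame_len, x$cfg$hop,
              x$cfg$fft_size, x$n_samples_original))
  invisible(x)
}

#' Convert log-power spectrum to magnitude
#'
#' The inverse of the LPS transform on the magnitude scale:
#' `magnitude = exp(lps / 2)` (exponential then square root), elementwise and
#' strictly positive.
#'
#' @param lps Numeric matrix (or vector) of log powers.
#' @return Magnitudes with the same shape.
#' @export
lps_to_magnitude <- function(lps) {
  if (!all(is.finite(lps))) stop_invalid("non-finite LPS input")
  exp(lps / 2)
}

#' Inverse STFT from log-power spectrum and phase
#'
#' Rebuilds complex spectra as `exp(lps/2) * exp(i * phase)`, inverts each
#' frame, and overlap-adds with a second application of the analysis window,
#' normalizing by the accumulated squared window. With the default Hann/50%
#' configuration this reconstructs the analysed signal to floating-point
#' accuracy away from the first and last half-frame.
#'
#' @param lps,phase Matrices (frames x bins) of equal shape.
#' @param cfg The [stft_config()] used for analysis.
#' @param n_samples Output length in samples (typically
#'   `n_samples_original` from [stft_analyze()]).
#' @param rate Sampling rate of the returned waveform.
#' @return An `eanr_wave` of exactly `n_samples` samples.
#' @export
stft_synthesize <- function(lps, phase, cfg, n_samples, rate = 16000) {
  if (!identical(dim(lps), dim(phase))) stop_invalid("lps/phase shape mismatch")
  bins <- cfg$fft_size %/% 2L + 1L
  if (ncol(lps) != bins) stop_invalid("expected %d bins, got %d", bins, ncol(lps))
  nf <- nrow(lps)
  Z <- t(lps_to_magnitude(lps) * exp(1i * phase)) # bins x frames
  full <- rbind(Z, Conj(Z[(bins - 1L):2L, , drop = FALSE]))
  fr <- Re(stats::mvfft(full, inverse = TRUE)) / cfg$fft_size
  fr <- fr[seq_len(cfg$frame_len), , drop = FALSE]
  win <- stft_window(cfg)
  n_total <- (nf - 1L) * cfg$hop + cfg$frame_len
  y <- numeric(n_total)
  wsum <- numeric(n_total)
  for (j in seq_len(nf)) {
    idx <- ((j - 1L) * cfg$hop + 1L):((j - 1L) * cfg$hop + cfg$frame_len)
    y[idx] <- y[idx] + fr[, j] * win
    wsum[idx] <- wsum[idx] + win^2
  }
  y <- y / pmax(wsum, 1e-8)
  if (n_samples <= n_total) y <- y[seq_len(n_samples)] else y <- c(y, numeric(n_samples - n_total))
  waveform(y, rate)
}

# ---------------------------------------------------------------------------
# MFCC
# ---------------------------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, n_mels x bins.
mel_filterbank <- function(rate, fft_size, n_mels, fmin, fmax) {
  bins <- fft_size %/% 2L + 1L
  f_bin <- (seq_len(bins) - 1) * rate / fft_size
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; cen <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (f_bin - lo) / (cen - lo)
    down <- (hi - f_bin) / (hi - cen)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix, n_out x n_in. Row 1 is the constant basis, so a
# uniform offset of the log-mel energies moves only coefficient 0.
dct_matrix <- function(n_out, n_in) {
  D <- matrix(0, n_out, n_in)
  for (k in 0:(n_out - 1L)) {
    D[k + 1L, ] <- cos(pi * k * (seq_len(n_in) - 0.5) / n_in) *
      if (k == 0L) sqrt(1 / n_in) else sqrt(2 / n_in)
  }
  D
}

#' Extract mel-frequency cepstral coefficients
#'
#' Standard chain: floored STFT power spectrum -> triangular mel filterbank ->
#' log -> orthonormal DCT-II. Framing is identical to [stft_analyze()] (same
#' config), so MFCC and LPS matrices from the same signal are frame-aligned.
#'
#' @param wave An `eanr_wave`.
#' @param cfg An [stft_config()].
#' @param n_mfcc Number of cepstral coefficients kept (including c0).
#' @param n_mels Number of mel filters.
#' @param fmin,fmax Filterbank frequency range in Hz (`fmax = NULL` means the
#'   Nyquist frequency).
#' @return An object of class `eanr_mfcc` with a `coeffs` matrix
#'   (frames x n_mfcc) and the settings in `cfg`.
#' @export
mfcc_extract <- function(wave, cfg = stft_config(), n_mfcc = 13L, n_mels = 26L,
                         fmin = 20, fmax = NULL) {
  fr <- stft_analyze(wave, cfg)
  fmax <- fmax %||% (wave$rate / 2)
  fb <- mel_filterbank(wave$rate, cfg$fft_size, n_mels, fmin, fmax)
  pow <- exp(fr$lps)                        # frames x bins, already floored
  logmel <- log(pmax(pow %*% t(fb), cfg$log_floor))
  D <- dct_matrix(n_mfcc, n_mels)
  structure(list(coeffs = logmel %*% t(D),
                 cfg = list(stft = cfg, n_mfcc = n_mfcc, n_mels = n_mels,
                            fmin = fmin, fmax = fmax, rate = wave$rate)),
            class = "eanr_mfcc")
}

#' @export
print.eanr_mfcc <- function(x, ...) {
  cat(sprintf("<eanr_mfcc> %d frames x %d coefficients\n",
              nrow(x$coeffs), ncol(x$coeffs)))
  invisible(x)
}
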