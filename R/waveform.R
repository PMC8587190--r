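#' Construct a mono waveform
#'
#' The unit of audio exchange throughout the package: a finite, real-valued
#' sample sequence with a sampling rate. Amplitudes are dimensionless with a
#' nominal range of \[-1, 1\] (enforced only on file output).
#'
#' @param samples Numeric vector of samples; all values must be finite.
#' @param rate Sampling rate in Hz (default 16000, the rate assumed by the
#'   noise-reduction pipeline).
#' @return An object of class `eanr_wave` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:15999) / 16000))
#' wave_duration(w)
#' @export
waveform <- function(samples, rate = 16000) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_invalid("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop_invalid("all samples must be finite")
  check_scalar_num(rate, "rate", lower = 1e-9)
  structure(list(samples = as.double(samples), rate = as.double(rate)),
            class = "eanr_wave")
}

is_wave <- function(x) inherits(x, "eanr_wave")

as_wave <- function(x, rate = 16000) {
  if (is_wave(x)) x else waveform(x, rate)
}

#' @export
print.eanr_wave <- function(x, ...) {
  cat(sprintf("<eanr_wave> %d samples @ %g Hz (%.3f s), peak %.4f, RMS %.4f\n",
              length(x$samples), x$rate, wave_duration(x),
              max(abs(x$samples)), wave_rms(x)))
  invisible(x)
}

#' Duration, RMS and mean power of a waveform
#'
#' @param wave An `eanr_wave`.
#' @return A single number: seconds, root-mean-square amplitude, or mean
#'   squared amplitude respectively.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$rate

#' @rdname wave_duration
#' @export
wave_rms <- function(wave) sqrt(mean(wave$samples^2))

#' @rdname wave_duration
#' @export
wave_power <- function(wave) mean(wave$samples^2)

# Scale a waveform to an exact RMS target. Zero-power input is degenerate.
#' Normalize a waveform to a target RMS amplitude
#'
#' @param wave An `eanr_wave`.
#' @param target_rms Desired root-mean-square amplitude (default 0.05, the
#'   pre-mixing speech level used by the corpus builder so that mixtures stay
#'   clear of clipping down to -10 dB SNR).
#' @return The rescaled waveform.
#' @export
wave_normalize_rms <- function(wave, target_rms = 0.05) {
  check_scalar_num(target_rms, "target_rms", lower = 1e-12)
  r <- wave_rms(wave)
  if (r <= 0) stop_invalid("cannot normalize a zero-power waveform")
  waveform(wave$samples * (target_rms / r), wave$rate)
}

# ---------------------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer (mono, PCM 16-bit or IEEE float32).
# ---------------------------------------------------------------------------

#' Read and write mono WAV files
#'
#' Supports RIFF PCM 16-bit and IEEE float32, mono. `write_wav` clips samples
#' to \[-1, 1\] for the 16-bit format.
#'
#' @param path File path.
#' @param wave An `eanr_wave`.
#' @param format `"pcm16"` or `"float32"`.
#' @return `read_wav` returns an `eanr_wave`; `write_wav` returns `path`
#'   invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave_id <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave_id, "WAVE")) stop_invalid("not a WAVE file: %s", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop_invalid("no data chunk in %s", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        code = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_invalid("data chunk before fmt chunk in %s", path)
      if (fmt$channels != 1L) stop_invalid("only mono WAV supported (got %d channels)", fmt$channels)
      if (fmt$code == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        x <- readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little") / 32767
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        x <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop_invalid("unsupported WAV format (code %d, %d bits)", fmt$code, fmt$bits)
      }
      return(waveform(x, fmt$rate))
    } else {
      readBin(con, "raw", sz + sz %% 2L) # skip unknown chunk (word-aligned)
    }
  }
}

#' @rdname read_wav
#' @export
write_wav <- function(wave, path, format = c("pcm16", "float32")) {
  stopifnot(is_wave(wave))
  format <- match.arg(format)
  x <- wave$samples
  n <- length(x)
  rate <- as.integer(round(wave$rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bytes_per <- 2L; code <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; code <- 3L; bits <- 32L
  }
  data_sz <- n * bytes_per
  fact_sz <- if (format == "float32") 12L else 0L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(4L + 24L + fact_sz + 8L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")           # block align
  writeBin(bits, con, size = 2, endian = "little")
  if (format == "float32") {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(as.integer(n), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(pmax(-1, pmin(1, x)) * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
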