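#' In-memory audio signal
#'
#' A light container for a sampled waveform. `samples` is a numeric vector
#' (mono) or a samples-by-channels matrix (multichannel); amplitudes are
#' expected in \[-1, 1\].
#'
#' @param samples Numeric vector or matrix of finite amplitudes.
#' @param sample_rate Sampling rate in Hz (positive).
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' a <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(a)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (length(samples) == 0L) {
    stop_invalid("`samples` must be non-empty.")
  }
  if (!all(is.finite(samples))) {
    stop_invalid("`samples` must be finite.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop_invalid("`sample_rate` must be a single positive number.")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf(
    "<audio_signal: %.3f s, %g Hz, %d channel%s>\n",
    duration(x), x$sample_rate, ch, if (ch > 1) "s" else ""
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param audio An `audio_signal`.
#' @return Length in seconds.
#' @export
duration <- function(audio) {
  n <- if (is.matrix(audio$samples)) nrow(audio$samples) else length(audio$samples)
  n / audio$sample_rate
}

as_mono <- function(audio) {
  if (is.matrix(audio$samples)) {
    audio$samples <- rowMeans(audio$samples)
  }
  audio
}

#' Resample audio to the analysis rate
#'
#' Averages multichannel input to mono, then resamples with a polyphase
#' filter to `target_rate` (default 8 kHz, the rate all envelope analysis
#' runs at).
#'
#' @param audio An `audio_signal`.
#' @param target_rate Target sampling rate in Hz.
#' @return A mono `audio_signal` at `target_rate`.
#' @export
resample_audio <- function(audio, target_rate = 8000) {
  if (!inherits(audio, "audio_signal")) {
    stop_invalid("`audio` must be an audio_signal.")
  }
  if (target_rate <= 0) {
    stop_invalid("`target_rate` must be positive.")
  }
  audio <- as_mono(audio)
  if (audio$sample_rate == target_rate) {
    return(audio)
  }
  g <- gcd(round(audio$sample_rate), round(target_rate))
  p <- round(target_rate) / g
  q <- round(audio$sample_rate) / g
  y <- signal::resample(audio$samples, p, q)
  n_expect <- ceiling(length(audio$samples) * p / q)
  y <- y[seq_len(min(length(y), n_expect))]
  audio_signal(pmin(1, pmax(-1, y)), target_rate)
}

gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Read a RIFF/WAVE file
#'
#' Supports PCM 8/16/24/32-bit and IEEE float 32/64, mono or multichannel.
#' Samples are scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return An `audio_signal` (matrix samples if multichannel).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(paste0("No such file: ", path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_parse(paste0("Not a RIFF file: ", path))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_parse(paste0("Not a WAVE file: ", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_parse(paste0("Missing fmt/data chunk in ", path))
  }
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (n == 0L) stop_parse(paste0("Empty data chunk in ", path))
  x <- if (fmt$format == 3L) {
    readBin(data_raw, "double", n, bytes, endian = "little")
  } else if (fmt$bits == 8L) {
    (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", n, 2, endian = "little") / 32767
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
  } else {
    stop_parse(sprintf("Unsupported WAV encoding (%d-bit, format %d)", fmt$bits, fmt$format))
  }
  if (fmt$channels > 1L) {
    x <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  }
  audio_signal(x, fmt$rate)
}

#' Write audio to a 16-bit PCM WAVE file
#'
#' @param audio An `audio_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  x <- audio$samples
  ch <- if (is.matrix(x)) ncol(x) else 1L
  if (is.matrix(x)) x <- as.vector(t(x))
  pcm <- as.integer(round(pmin(1, pmax(-1, x)) * 32767))
  rate <- as.integer(round(audio$sample_rate))
  block <- 2L * ch
  data_sz <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, ch), con, 2, endian = "little")
  writeBin(c(rate, rate * block), con, 4, endian = "little")
  writeBin(c(block, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
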