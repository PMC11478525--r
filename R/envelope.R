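#' Triangular Mel filterbank
#'
#' Builds `n_mels` triangular filters with unit peak, spanning `fmin` to
#' `fmax` on the HTK Mel scale (2595 log10(1 + f/700)).
#'
#' @param n_mels Number of bands.
#' @param n_fft FFT length the filters apply to.
#' @param sample_rate Sampling rate in Hz.
#' @param fmin,fmax Frequency span in Hz; `fmax` defaults to Nyquist.
#' @return A `n_mels` x `(n_fft/2 + 1)` matrix with attribute `band_edges`,
#'   a tibble of the lower/centre/upper edge of each band in Hz.
#' @export
mel_filterbank <- function(n_mels = 40, n_fft = 256, sample_rate = 8000,
                           fmin = 0, fmax = sample_rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2 + 1
  bin_hz <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges_hz <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (b in seq_len(n_mels)) {
    lo <- edges_hz[b]; ce <- edges_hz[b + 1]; hi <- edges_hz[b + 2]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "band_edges") <- tibble(
    band = seq_len(n_mels),
    f_lo_hz = edges_hz[seq_len(n_mels)],
    f_center_hz = edges_hz[seq_len(n_mels) + 1],
    f_hi_hz = edges_hz[seq_len(n_mels) + 2]
  )
  fb
}

#' Mel-band log-power spectrogram
#'
#' Short-time Fourier magnitudes (Hann window, no padding: every frame lies
#' fully inside the signal) pooled into Mel bands and converted to dB
#' relative to the strongest band-frame, floored at `db_floor`.
#'
#' Frame timestamps use the centre of the analysis window
#' (`t_k = (k-1) hop + window/2`), the usual short-time convention; with it
#' the onset-envelope peak of an isolated percussive event sits within
#' about one hop of the event's true onset time.
#'
#' @param audio Mono `audio_signal` at the analysis rate.
#' @param window_s Window length in seconds (default 32 ms).
#' @param hop_s Hop between frames in seconds (default 4 ms).
#' @param n_mels Number of Mel bands (default 40).
#' @param db_floor Dynamic-range floor in dB (default -80).
#' @return A `mel_frames` object: `band_energies_db` (frames x bands),
#'   `hop_seconds`, `window_seconds`, `frame_times`.
#' @export
mel_spectrogram <- function(audio, window_s = 0.032, hop_s = 0.004,
                            n_mels = 40, db_floor = -80) {
  if (!inherits(audio, "audio_signal")) stop_invalid("`audio` must be an audio_signal.")
  if (is.matrix(audio$samples)) audio <- as_mono(audio)
  if (!(window_s > hop_s && hop_s > 0)) {
    stop_invalid("Need `window_s` > `hop_s` > 0.")
  }
  x <- audio$samples
  rate <- audio$sample_rate
  win <- round(window_s * rate)
  hop <- round(hop_s * rate)
  if (length(x) < win) {
    stop_invalid("Signal shorter than one analysis window.")
  }
  n_frames <- (length(x) - win) %/% hop + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = win)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  spec <- Mod(mvfft(frames * hann))^2
  spec <- spec[seq_len(win %/% 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(n_mels, n_fft = win, sample_rate = rate)
  mel_power <- fb %*% spec
  ref <- max(mel_power)
  floor_lin <- 10^(db_floor / 10)
  db <- if (ref <= 0) {
    matrix(db_floor, nrow(mel_power), ncol(mel_power))
  } else {
    10 * log10(pmax(mel_power / ref, floor_lin))
  }
  structure(
    list(
      band_energies_db = t(db),
      hop_seconds = hop / rate,
      window_seconds = win / rate,
      frame_times = (seq_len(n_frames) - 1L) * hop / rate + win / (2 * rate),
      db_floor = db_floor
    ),
    class = "mel_frames"
  )
}

#' @export
print.mel_frames <- function(x, ...) {
  cat(sprintf(
    "<mel_frames: %d frames x %d bands, hop %.1f ms, window %.1f ms>\n",
    nrow(x$band_energies_db), ncol(x$band_energies_db),
    1000 * x$hop_seconds, 1000 * x$window_seconds
  ))
  invisible(x)
}

#' Onset strength envelope
#'
#' Per-band first-order dB differences are half-wave rectified and summed
#' across bands, high-passed (first-order Butterworth, zero phase) so the
#' local mean sits near zero, smoothed with a Gaussian kernel, and divided
#' by the standard deviation so downstream weights are scale-free.
#'
#' @param frames A `mel_frames` object.
#' @param hp_cutoff_hz High-pass cutoff in Hz (default 0.4).
#' @param smooth_sigma_s Gaussian smoothing standard deviation in seconds
#'   (default 20 ms); the kernel is truncated at four sigma and sums to one.
#' @return An `onset_envelope`: `values` (unit standard deviation),
#'   `hop_seconds`, `frame_times`, `normalized = TRUE`.
#' @export
onset_envelope <- function(frames, hp_cutoff_hz = 0.4, smooth_sigma_s = 0.020) {
  if (!inherits(frames, "mel_frames")) stop_invalid("`frames` must be mel_frames.")
  db <- frames$band_energies_db
  hop <- frames$hop_seconds
  d <- diff(db)                       # (n-1) x bands
  flux <- c(0, rowSums(pmax(d, 0)))   # leading 0 keeps length = n_frames
  if (all(flux == 0) || sd(flux) == 0) {
    stop_degenerate("Onset envelope is constant; no energy changes to track.")
  }
  frame_rate <- 1 / hop
  bf <- signal::butter(1, hp_cutoff_hz / (frame_rate / 2), type = "high")
  hp <- signal::filtfilt(bf, flux)
  smoothed <- gaussian_smooth(hp, sigma = smooth_sigma_s / hop)
  s <- sd(smoothed)
  if (!is.finite(s) || s == 0) {
    stop_degenerate("Onset envelope has zero variance after filtering.")
  }
  structure(
    list(
      values = smoothed / s,
      hop_seconds = hop,
      frame_times = frames$frame_times,
      normalized = TRUE
    ),
    class = "onset_envelope"
  )
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  padded <- c(numeric(half), x, numeric(half))
  y <- stats::filter(padded, k, sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Construct an onset envelope from raw values
#'
#' Wraps an arbitrary strength series as an `onset_envelope`, dividing by
#' its standard deviation. Used to feed the beat tracker with synthetic or
#' externally computed envelopes.
#'
#' @param values Numeric strength series.
#' @param hop_seconds Time step between values in seconds.
#' @param t0 Timestamp of the first value (default 0).
#' @return An `onset_envelope`.
#' @export
as_onset_envelope <- function(values, hop_seconds, t0 = 0) {
  if (length(values) < 2L || !all(is.finite(values))) {
    stop_invalid("`values` must be a finite series of length >= 2.")
  }
  if (hop_seconds <= 0) stop_invalid("`hop_seconds` must be positive.")
  s <- sd(values)
  if (s == 0) stop_degenerate("Cannot normalize a constant envelope.")
  structure(
    list(
      values = values / s,
      hop_seconds = hop_seconds,
      frame_times = t0 + (seq_along(values) - 1L) * hop_seconds,
      normalized = TRUE
    ),
    class = "onset_envelope"
  )
}

#' @export
print.onset_envelope <- function(x, ...) {
  cat(sprintf(
    "<onset_envelope: %d frames, hop %.1f ms, span %.2f s>\n",
    length(x$values), 1000 * x$hop_seconds, diff(range(x$frame_times))
  ))
  invisible(x)
}
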