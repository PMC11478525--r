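#' Track beats by dynamic programming
#'
#' Finds the beat instants maximising cumulative onset strength minus a
#' spacing penalty. For each envelope frame `t` the best score is
#' `C*(t) = O(t) + max over tau in [t - hi*tau_p, t - lo*tau_p] of
#' (omega * F(t - tau, tau_p) + C*(tau))` with [transition_cost()] `F`;
#' the predecessor attaining the maximum is recorded (earliest wins on
#' ties). Frames too early to have an admissible predecessor start new
#' chains with `C*(t) = O(t)`. The final beat is the highest-scoring frame
#' in the last `tau_p` of the envelope, and the sequence is recovered by
#' backtracking.
#'
#' Consecutive beat intervals are therefore confined to
#' `[window_lo_factor, window_hi_factor] * tau_p` by construction; the
#' tracker bridges silent stretches with low-strength beats rather than
#' stopping (see [prune_weak_beats()] for the gap-handling pipeline).
#'
#' @param env An `onset_envelope`.
#' @param tempo A `tempo_estimate` or the tempo period in seconds.
#' @param omega Transition weight balancing onset strength against spacing
#'   regularity (default 100).
#' @param window_lo_factor,window_hi_factor Predecessor search window as
#'   multiples of `tau_p` (defaults 0.5 and 2).
#' @return A tibble of class `beat_sequence` with columns `time_s` (strictly
#'   increasing), `frame`, `score` (`C*`), and `strength` (envelope value at
#'   the beat); attributes `tau_p` and `hop_seconds`.
#' @export
track_beats <- function(env, tempo, omega = 100,
                        window_lo_factor = 0.5, window_hi_factor = 2.0) {
  if (!inherits(env, "onset_envelope")) stop_invalid("`env` must be an onset_envelope.")
  tau_p <- if (inherits(tempo, "tempo_estimate")) tempo$tau_p else as.numeric(tempo)
  if (!is.finite(tau_p) || tau_p <= 0) stop_invalid("`tau_p` must be positive.")
  if (omega <= 0) stop_invalid("`omega` must be positive.")
  if (!(window_lo_factor > 0 && window_lo_factor < 1 && window_hi_factor > 1)) {
    stop_invalid("Need 0 < window_lo_factor < 1 < window_hi_factor.")
  }
  o <- env$values
  hop <- env$hop_seconds
  n <- length(o)
  if (n * hop < tau_p) {
    stop_insufficient("Envelope shorter than one tempo period.")
  }
  dmin <- max(1L, ceiling(window_lo_factor * tau_p / hop - 1e-9))
  dmax <- max(dmin, floor(window_hi_factor * tau_p / hop + 1e-9))
  pen <- omega * transition_cost((dmin:dmax) * hop, tau_p)

  cstar <- numeric(n)
  pstar <- integer(n)  # 0 = chain start
  for (t in seq_len(n)) {
    hi <- t - dmin
    if (hi < 1L) {
      cstar[t] <- o[t]
      next
    }
    lo <- max(1L, t - dmax)
    taus <- lo:hi
    scores <- cstar[taus] + pen[(t - taus) - dmin + 1L]
    j <- which.max(scores)  # first max = earliest predecessor
    cstar[t] <- o[t] + scores[j]
    pstar[t] <- taus[j]
  }

  tail_len <- min(n, max(1L, floor(tau_p / hop)))
  tail_idx <- (n - tail_len + 1L):n
  t_final <- tail_idx[which.max(cstar[tail_idx])]

  chain <- integer(0)
  t_cur <- t_final
  while (t_cur > 0L) {
    chain <- c(t_cur, chain)
    t_cur <- pstar[t_cur]
  }

  out <- tibble(
    time_s = env$frame_times[chain],
    frame = chain,
    score = cstar[chain],
    strength = o[chain]
  )
  attr(out, "tau_p") <- tau_p
  attr(out, "hop_seconds") <- hop
  attr(out, "omega") <- omega
  attr(out, "window_factors") <- c(window_lo_factor, window_hi_factor)
  class(out) <- c("beat_sequence", class(out))
  out
}

#' Compare detected beats against a reference annotation
#'
#' Greedy one-to-one matching: each detected beat is paired with the nearest
#' unmatched reference beat within `window` seconds. Reports precision,
#' recall, their harmonic mean (F-measure), and the mean absolute timing
#' error of matched pairs.
#'
#' @param detected Numeric vector of detected beat times (s), or a
#'   `beat_sequence`.
#' @param reference Numeric vector of ground-truth beat times (s).
#' @param window Match tolerance in seconds (default 0.07).
#' @return A one-row tibble: `f_measure`, `precision`, `recall`, `mae_s`,
#'   `n_matched`, `n_detected`, `n_reference`.
#' @export
beat_f_measure <- function(detected, reference, window = 0.07) {
  if (inherits(detected, "beat_sequence")) detected <- detected$time_s
  if (length(reference) == 0L) stop_invalid("`reference` must be non-empty.")
  used <- logical(length(reference))
  errs <- numeric(0)
  for (t in detected) {
    d <- abs(reference - t)
    d[used] <- Inf
    k <- which.min(d)
    if (is.finite(d[k]) && d[k] <= window) {
      used[k] <- TRUE
      errs <- c(errs, d[k])
    }
  }
  n_match <- sum(used)
  precision <- if (length(detected)) n_match / length(detected) else 0
  recall <- n_match / length(reference)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(
    f_measure = f,
    precision = precision,
    recall = recall,
    mae_s = if (n_match) mean(errs) else NA_real_,
    n_matched = n_match,
    n_detected = length(detected),
    n_reference = length(reference)
  )
}

#' Write beats to CSV / JSON
#'
#' The CSV holds one `time_s` column; the JSON document carries the tempo,
#' beat times, and tracker configuration.
#'
#' @param beats A `beat_sequence`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return `beats`, invisibly.
#' @export
write_beats <- function(beats, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(data.frame(time_s = beats$time_s), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    tau_p <- attr(beats, "tau_p")
    doc <- list(
      tempo_bpm = 60 / tau_p,
      tau_p_s = tau_p,
      beat_times_s = beats$time_s,
      config = list(
        omega = attr(beats, "omega"),
        window_lo_factor = attr(beats, "window_factors")[1],
        window_hi_factor = attr(beats, "window_factors")[2],
        hop_seconds = attr(beats, "hop_seconds")
      )
    )
    jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(beats)
}

#' Full audio-to-beats pipeline
#'
#' Convenience wrapper: resample to the analysis rate, compute the Mel
#' spectrogram and onset envelope, estimate the tempo, and track beats.
#'
#' @param audio An `audio_signal`.
#' @param analysis_rate Analysis sampling rate in Hz.
#' @param window_s,hop_s,n_mels,db_floor See [mel_spectrogram()].
#' @param hp_cutoff_hz,smooth_sigma_s See [onset_envelope()].
#' @param tau0,sigma_oct,lag_range See [estimate_tempo()].
#' @param omega,window_lo_factor,window_hi_factor See [track_beats()].
#' @return A list with `beats` (`beat_sequence`), `tempo`
#'   (`tempo_estimate`), and `envelope` (`onset_envelope`).
#' @export
detect_beats <- function(audio,
                         analysis_rate = 8000,
                         window_s = 0.032, hop_s = 0.004,
                         n_mels = 40, db_floor = -80,
                         hp_cutoff_hz = 0.4, smooth_sigma_s = 0.020,
                         tau0 = 0.5, sigma_oct = 1.0, lag_range = c(0.2, 2.0),
                         omega = 100,
                         window_lo_factor = 0.5, window_hi_factor = 2.0) {
  a <- resample_audio(audio, analysis_rate)
  frames <- mel_spectrogram(a, window_s, hop_s, n_mels, db_floor)
  env <- onset_envelope(frames, hp_cutoff_hz, smooth_sigma_s)
  tempo <- estimate_tempo(env, tau0, sigma_oct, lag_range)
  beats <- track_beats(env, tempo, omega, window_lo_factor, window_hi_factor)
  list(beats = beats, tempo = tempo, envelope = env)
}
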