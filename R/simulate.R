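with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a ground-truthed click track
#'
#' Sinusoidal click bursts (default 30 ms at 1 kHz with 5 ms linear fades)
#' placed at exact multiples of the beat period `60 / bpm`; the sample
#' index of click `k` is `round(k * 60 / bpm * sample_rate)`. Optional
#' white noise at a stated SNR (relative to the click signal power) and
#' silent gaps where the waveform — clicks included — is zeroed. True beat
#' times are returned exactly; identical specs (seed included) give
#' bitwise-identical samples.
#'
#' @param bpm Tempo in beats per minute.
#' @param duration_s Track length in seconds.
#' @param sample_rate Sampling rate in Hz (default 8000).
#' @param click_freq_hz Click carrier frequency (default 1000).
#' @param click_dur_s Click length in seconds (default 0.03).
#' @param noise_snr_db Signal-to-noise ratio in dB, or `NULL` for none.
#' @param silent_gaps List of `c(start, end)` pairs in seconds; audio is
#'   zeroed on `[start, end)` and true beats there are removed.
#' @param seed Integer seed for the noise (only source of randomness).
#' @return List with `audio` (an `audio_signal`) and `beat_times` (s).
#' @examples
#' ct <- generate_click_track(bpm = 120, duration_s = 10)
#' length(ct$beat_times)  # 20
#' @export
generate_click_track <- function(bpm = 120, duration_s = 30, sample_rate = 8000,
                                 click_freq_hz = 1000, click_dur_s = 0.030,
                                 noise_snr_db = NULL, silent_gaps = NULL,
                                 seed = NULL) {
  if (bpm <= 0 || duration_s <= 0 || sample_rate <= 0) {
    stop_invalid("`bpm`, `duration_s`, and `sample_rate` must be positive.")
  }
  if (!is.null(silent_gaps)) {
    for (g in silent_gaps) {
      if (length(g) != 2L || g[1] >= g[2] || g[1] < 0 || g[2] > duration_s) {
        stop_invalid("Each silent gap must be c(start, end) within [0, duration].")
      }
    }
  }
  period <- 60 / bpm
  n <- round(duration_s * sample_rate)
  x <- numeric(n)

  click_n <- round(click_dur_s * sample_rate)
  fade_n <- min(round(0.005 * sample_rate), click_n %/% 2)
  envl <- rep(1, click_n)
  if (fade_n > 0) {
    ramp <- seq_len(fade_n) / fade_n
    envl[seq_len(fade_n)] <- ramp
    envl[(click_n - fade_n + 1):click_n] <- rev(ramp)
  }
  burst <- 0.8 * sin(2 * pi * click_freq_hz * (seq_len(click_n) - 1) / sample_rate) * envl

  all_beats <- (seq_len(ceiling(duration_s / period)) - 1) * period
  all_beats <- all_beats[all_beats < duration_s]
  for (t in all_beats) {
    s0 <- round(t * sample_rate) + 1L
    s1 <- min(n, s0 + click_n - 1L)
    x[s0:s1] <- x[s0:s1] + burst[seq_len(s1 - s0 + 1L)]
  }

  if (!is.null(noise_snr_db)) {
    p_sig <- mean(x^2)
    sd_n <- sqrt(p_sig / 10^(noise_snr_db / 10))
    x <- x + with_local_seed(seed, rnorm(n, sd = sd_n))
  }

  in_gap <- function(t) {
    if (is.null(silent_gaps)) return(rep(FALSE, length(t)))
    Reduce(`|`, lapply(silent_gaps, function(g) t >= g[1] & t < g[2]))
  }
  if (!is.null(silent_gaps)) {
    samp_t <- (seq_len(n) - 1) / sample_rate
    x[in_gap(samp_t)] <- 0
  }
  beat_times <- all_beats[!in_gap(all_beats)]

  list(
    audio = audio_signal(pmin(1, pmax(-1, x)), sample_rate),
    beat_times = beat_times
  )
}

#' Generate a paired standard/perturbed pose-angle sequence
#'
#' The standard performance draws each feature's angle trajectory from a
#' sum of two to four low-frequency sinusoids (smooth, dance-like, bounded
#' in \[20, 175\] degrees). The evaluated performance is the standard plus
#' Gaussian angular noise, an optional linear drift (systematic error), and
#' random dropout to absent (`NA`). Identical specs (seed included) give
#' identical sequences.
#'
#' @param n_frames Number of keyframes.
#' @param feature_def Feature definition (names give the columns).
#' @param angle_noise_sd Angular noise standard deviation in degrees.
#' @param dropout_prob Per-entry probability of an absent angle in the
#'   evaluated sequence.
#' @param drift Systematic error in degrees per frame.
#' @param beat_interval_s Keyframe spacing in seconds (default 0.5).
#' @param seed Integer seed.
#' @return List with `standard` and `evaluated` (`pose_description`s).
#' @export
generate_pose_pair <- function(n_frames, feature_def = default_feature_def(),
                               angle_noise_sd = 0, dropout_prob = 0, drift = 0,
                               beat_interval_s = 0.5, seed = NULL) {
  if (n_frames < 1) stop_invalid("`n_frames` must be >= 1.")
  if (angle_noise_sd < 0 || dropout_prob < 0 || dropout_prob > 1) {
    stop_invalid("Noise parameters must be nonnegative (dropout in [0, 1]).")
  }
  m <- nrow(feature_def)
  with_local_seed(seed, {
    tt <- seq_len(n_frames)
    std <- vapply(seq_len(m), function(j) {
      centre <- runif(1, 70, 120)
      k <- sample(2:4, 1)
      traj <- rep(centre, n_frames)
      for (h in seq_len(k)) {
        amp <- runif(1, 5, 45 / k)
        freq <- runif(1, 0.01, 0.15)  # cycles per keyframe
        phase <- runif(1, 0, 2 * pi)
        traj <- traj + amp * sin(2 * pi * freq * tt + phase)
      }
      pmin(175, pmax(20, traj))
    }, numeric(n_frames))
    std <- matrix(std, nrow = n_frames)

    ev <- std +
      matrix(rnorm(n_frames * m, sd = angle_noise_sd), n_frames, m) +
      drift * (tt - 1)
    ev <- pmin(pmax(ev, 0), 180)
    if (dropout_prob > 0) {
      drop <- matrix(runif(n_frames * m) < dropout_prob, n_frames, m)
      ev[drop] <- NA_real_
    }

    beat_times <- (tt - 1) * beat_interval_s
    list(
      standard = as_pose_description(std, beat_times, feature_def),
      evaluated = as_pose_description(ev, beat_times, feature_def)
    )
  })
}
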