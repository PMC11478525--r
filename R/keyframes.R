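#' Map beat instants to video keyframe indices
#'
#' Each beat time is rounded (half away from zero) to the nearest 0-based
#' frame index at the video frame rate. Indices beyond the last frame are
#' dropped with a warning; duplicate indices (possible at high tempo / low
#' frame rate) are collapsed keeping the first beat's time.
#'
#' @param beats A `beat_sequence` or a data frame with a `time_s` column.
#' @param fps Video frame rate (frames per second).
#' @param n_frames Number of frames in the video; `Inf` disables the bound.
#' @return A tibble of class `keyframe_sequence` with columns `beat_time_s`
#'   and `frame_index` (strictly increasing); attribute `fps`.
#' @examples
#' beats_to_keyframes(data.frame(time_s = c(0.5, 1.0, 1.5)), fps = 30)
#' @export
beats_to_keyframes <- function(beats, fps, n_frames = Inf) {
  times <- beat_times_of(beats)
  if (length(times) == 0L) stop_invalid("Beat sequence is empty.")
  if (!is.numeric(fps) || fps <= 0) stop_invalid("`fps` must be positive.")
  if (!(is.numeric(n_frames) && (is.infinite(n_frames) || n_frames >= 0))) {
    stop_invalid("`n_frames` must be a non-negative count.")
  }
  idx <- floor(times * fps + 0.5)  # round half away from zero (times >= 0)
  keep <- idx < n_frames
  if (any(!keep)) {
    warn(sprintf(
      "%d beat(s) beyond the last video frame dropped (frame count %g).",
      sum(!keep), n_frames
    ))
  }
  times <- times[keep]
  idx <- idx[keep]
  first <- !duplicated(idx)
  out <- tibble(beat_time_s = times[first], frame_index = as.integer(idx[first]))
  attr(out, "fps") <- fps
  class(out) <- c("keyframe_sequence", class(out))
  out
}

beat_times_of <- function(beats) {
  if (is.data.frame(beats)) {
    if (!"time_s" %in% names(beats)) stop_invalid("`beats` needs a `time_s` column.")
    beats$time_s
  } else if (is.numeric(beats)) {
    beats
  } else {
    stop_invalid("`beats` must be a beat_sequence, data frame, or numeric vector.")
  }
}

#' Drop beats with negligible onset support
#'
#' The dynamic-programming tracker bridges silent stretches with regularly
#' spaced beats that sit on near-zero onset strength. This filter removes
#' beats whose envelope strength falls below `min_fraction` of the median
#' beat strength, so that genuinely beat-free intervals (silence in the
#' music) become visible to [find_beat_gaps()] instead of being papered
#' over.
#'
#' @param beats A `beat_sequence` (needs the `strength` column).
#' @param min_fraction Strength threshold as a fraction of the median beat
#'   strength (default 0.1).
#' @return The filtered `beat_sequence`.
#' @export
prune_weak_beats <- function(beats, min_fraction = 0.1) {
  if (!"strength" %in% names(beats)) {
    stop_invalid("`beats` must carry a `strength` column (as from track_beats()).")
  }
  thr <- min_fraction * median(beats$strength)
  keep <- beats$strength >= thr
  out <- beats[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop_insufficient("All beats fell below the strength threshold.")
  attributes(out)[c("tau_p", "hop_seconds", "omega", "window_factors")] <-
    attributes(beats)[c("tau_p", "hop_seconds", "omega", "window_factors")]
  out
}

#' Report beat-free gaps
#'
#' Flags every consecutive beat interval longer than `factor` times the
#' median interval. Following the ignore-the-silence strategy, no keyframes
#' are synthesised inside gaps; `n_missing_expected` counts how many beats a
#' regular grid at the median interval would have placed there.
#'
#' @param beats A beat sequence (>= 2 beats).
#' @param factor Gap threshold as a multiple of the median interval
#'   (default 2; must exceed 1).
#' @return A tibble of class `gap_report` with columns `start_s`, `end_s`,
#'   `n_missing_expected`; attribute `median_interval_s`.
#' @export
find_beat_gaps <- function(beats, factor = 2) {
  times <- beat_times_of(beats)
  if (length(times) < 2L) stop_insufficient("Need at least two beats to measure intervals.")
  if (factor <= 1) stop_invalid("`factor` must exceed 1.")
  iv <- diff(times)
  med <- median(iv)
  is_gap <- iv > factor * med
  out <- tibble(
    start_s = times[which(is_gap)],
    end_s = times[which(is_gap) + 1L],
    n_missing_expected = as.integer(round(iv[is_gap] / med) - 1L)
  )
  attr(out, "median_interval_s") <- med
  class(out) <- c("gap_report", class(out))
  out
}

#' Fill beat gaps with synthetic beats
#'
#' The alternative gap strategy: inside each reported gap, insert beats at
#' the global tempo period. Inserted rows are flagged `synthetic = TRUE`.
#' Off by default throughout the package; the pipeline ignores gaps.
#'
#' @param beats A beat sequence data frame with `time_s`.
#' @param gaps A `gap_report` for the same beats.
#' @param tau_p Tempo period in seconds used for the synthetic spacing.
#' @return A tibble with columns `time_s` and `synthetic`, sorted by time.
#' @export
fill_beat_gaps <- function(beats, gaps, tau_p) {
  times <- beat_times_of(beats)
  if (tau_p <= 0) stop_invalid("`tau_p` must be positive.")
  synth <- numeric(0)
  for (i in seq_len(nrow(gaps))) {
    lo <- gaps$start_s[i]
    hi <- gaps$end_s[i]
    cand <- seq(lo + tau_p, hi - tau_p / 2, by = tau_p)
    synth <- c(synth, cand)
  }
  out <- tibble(
    time_s = c(times, synth),
    synthetic = c(rep(FALSE, length(times)), rep(TRUE, length(synth)))
  )
  out[order(out$time_s), ]
}

#' Write keyframes to CSV / JSON
#'
#' @param keyframes A `keyframe_sequence`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return `keyframes`, invisibly.
#' @export
write_keyframes <- function(keyframes, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(
      data.frame(
        beat_time_s = keyframes$beat_time_s,
        frame_index = keyframes$frame_index
      ),
      csv, row.names = FALSE
    )
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(
        fps = attr(keyframes, "fps"),
        beat_time_s = keyframes$beat_time_s,
        frame_index = keyframes$frame_index
      ),
      json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(keyframes)
}
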