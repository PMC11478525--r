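test_that("beat times map to rounded frame indices", {
  expect_equal(
    beats_to_keyframes(data.frame(time_s = 2.0), fps = 24)$frame_index, 48L
  )
  kf <- beats_to_keyframes(data.frame(time_s = c(0.5, 1.0, 1.5)), fps = 30)
  expect_equal(kf$frame_index, c(15L, 30L, 45L))
  expect_error(beats_to_keyframes(data.frame(time_s = numeric(0)), 24),
               class = "danceval_invalid_input")
})

test_that("indices beyond the video are dropped with a warning", {
  expect_warning(
    kf <- beats_to_keyframes(data.frame(time_s = c(1.0, 12.0)), fps = 24, n_frames = 240),
    "dropped"
  )
  expect_equal(kf$frame_index, 24L)
})

test_that("duplicate frame indices collapse to the first beat", {
  # 600 BPM at 5 fps: beats 0.1 s apart, frames 0.2 s apart
  kf <- beats_to_keyframes(data.frame(time_s = c(0.40, 0.44, 0.61)), fps = 5)
  expect_equal(kf$frame_index, c(2L, 3L))
  expect_equal(kf$beat_time_s[1], 0.40)
  expect_true(all(diff(kf$frame_index) > 0))
})

test_that("beats on the exact frame grid round-trip through indices", {
  fps <- 24
  times <- (0:40) * 3 / fps
  kf <- beats_to_keyframes(data.frame(time_s = times), fps = fps)
  expect_equal(kf$frame_index / fps, times)
})

test_that("keyframe fraction equals BPM / (60 fps) and spans the expected range", {
  fps <- 24
  dur <- 60
  frac_pct <- function(bpm) {
    beats <- data.frame(time_s = seq(0, dur - 1e-9, by = 60 / bpm))
    kf <- beats_to_keyframes(beats, fps = fps, n_frames = fps * dur)
    100 * nrow(kf) / (fps * dur)
  }
  for (bpm in c(59, 90, 120, 148)) {
    expect_equal(frac_pct(bpm), 100 * bpm / (60 * fps), tolerance = 0.02)
  }
  expect_equal(round(frac_pct(59), 1), 4.1)
  expect_equal(round(frac_pct(148), 1), 10.3)
})

test_that("removing beats never adds keyframes", {
  set.seed(21)
  times <- sort(runif(50, 0, 30))
  full <- beats_to_keyframes(data.frame(time_s = times), fps = 24)
  sub <- beats_to_keyframes(data.frame(time_s = times[-c(5, 9, 30)]), fps = 24)
  expect_lte(nrow(sub), nrow(full))
  expect_true(all(sub$frame_index %in% full$frame_index))
})

test_that("gap detection flags long intervals and nothing else", {
  regular <- data.frame(time_s = seq(0, 20, by = 0.5))
  expect_equal(nrow(find_beat_gaps(regular)), 0)

  times <- seq(0, 30, by = 0.5)
  times <- times[!(times > 10 & times < 15)]
  gaps <- find_beat_gaps(data.frame(time_s = times), factor = 2)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$start_s, 10)
  expect_equal(gaps$end_s, 15)
  expect_equal(gaps$n_missing_expected, 9L)

  expect_error(find_beat_gaps(data.frame(time_s = 1.0)),
               class = "danceval_insufficient_data")
  expect_error(find_beat_gaps(regular, factor = 1), class = "danceval_invalid_input")
})

test_that("gap filling inserts period-spaced synthetic beats only inside gaps", {
  times <- seq(0, 30, by = 0.5)
  times <- times[!(times > 10 & times < 15)]
  beats <- data.frame(time_s = times)
  gaps <- find_beat_gaps(beats)
  filled <- fill_beat_gaps(beats, gaps, tau_p = 0.5)
  synth <- filled$time_s[filled$synthetic]
  expect_true(all(synth > 10 & synth < 15))
  expect_equal(length(synth), 9)
  expect_false(is.unsorted(filled$time_s))
})

test_that("pruning weak beats exposes silent stretches to gap reporting", {
  ct <- generate_click_track(bpm = 120, duration_s = 30,
                             silent_gaps = list(c(10, 15)))
  res <- detect_beats(ct$audio)
  # the DP bridged the silence: no raw gap visible
  expect_equal(nrow(find_beat_gaps(res$beats)), 0)
  pruned <- prune_weak_beats(res$beats)
  gaps <- find_beat_gaps(pruned)
  expect_equal(nrow(gaps), 1)
  expect_lt(abs(gaps$start_s - 10), 0.6)
  expect_lt(abs(gaps$end_s - 15), 0.1)
  kf <- beats_to_keyframes(pruned, fps = 24, n_frames = 720)
  expect_equal(sum(kf$beat_time_s > 10.5 & kf$beat_time_s < 14.5), 0)
})
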