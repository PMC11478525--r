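test_that("cosine similarity matches hand values and handles absence", {
  expect_equal(cosine_similarity_seq(c(3, 1, 4), c(3, 1, 4)), 1)
  expect_equal(cosine_similarity_seq(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity_seq(c(1, 0), c(1, 1)), 1 / sqrt(2))
  # pairwise deletion
  expect_equal(cosine_similarity_seq(c(1, NA, 0), c(1, 5, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity_seq(c(NA, NA), c(1, 2)),
               class = "danceval_insufficient_data")
  expect_error(cosine_similarity_seq(c(NA, 1, 2), c(3, NA, 4)),
               class = "danceval_insufficient_data")
  expect_error(cosine_similarity_seq(c(0, 0), c(1, 1)),
               class = "danceval_undefined_similarity")
  expect_error(cosine_similarity_seq(1:3, 1:4), class = "danceval_invalid_input")
})

test_that("ASCS reproduces the two-feature worked example", {
  std <- make_pose(matrix(c(90, 90, 45, 135), 2))
  ev <- make_pose(matrix(c(90, 90, 90, 90), 2))
  br <- ascs_score(ev, std)
  # independent direct evaluation of the cosine formula
  s2 <- (90 * 45 + 90 * 135) / (sqrt(90^2 + 90^2) * sqrt(45^2 + 135^2))
  expect_equal(unname(br$s_per_feature), c(1, s2), tolerance = 1e-12)
  expect_equal(br$ascs_pct, 100 * (1 + s2) / 2, tolerance = 1e-9)
  expect_equal(br$ascs_pct, 94.7213595499958, tolerance = 1e-9)
})

test_that("ASCS is exact on identity and invariant to common scaling", {
  pair <- generate_pose_pair(n_frames = 15, seed = 4)
  expect_equal(ascs_score(pair$standard, pair$standard)$ascs_pct, 100)
  m <- angle_matrix(pair$standard)
  def <- attr(pair$standard, "feature_def")
  a <- as_pose_description(m / 2, pair$standard$beat_time_s, def)
  b <- as_pose_description(m / 4, pair$standard$beat_time_s, def)
  half <- ascs_score(a, b)
  expect_equal(unname(half$s_per_feature), rep(1, ncol(m)), tolerance = 1e-12)
})

test_that("binarization applies the inclusive threshold", {
  expect_equal(as.integer(binarize_scores(c(0.90, 0.80, 0.86), 0.85)), c(1L, 0L, 1L))
  expect_equal(as.integer(binarize_scores(rep(1, 4), 0.85)), rep(1L, 4))
  expect_equal(as.integer(binarize_scores(0.85, 0.85)), 1L)
  expect_error(binarize_scores(0.5, 0), class = "danceval_invalid_input")
  expect_error(binarize_scores(1.5, 0.85), class = "danceval_invalid_input")
})

test_that("LCS handles the documented instances", {
  expect_equal(lcs_length(rep(1L, 7), rep(1L, 7)), 7L)
  expect_equal(lcs_length(c(1, 0, 1, 0, 1), c(1, 1, 1, 1, 1)), 3L)
  expect_equal(lcs_bruteforce(c(1, 0, 1, 0, 1), c(1, 1, 1, 1, 1)), 3L)
  expect_equal(lcs_length(integer(0), c(1, 0)), 0L)
  expect_equal(lcs_length(c("a", "b", "a"), c("b", "a", "b")), 2L)
})

test_that("LCS equals exhaustive enumeration on all short binary pairs", {
  seqs <- unlist(
    lapply(1:5, function(n) {
      lapply(0:(2^n - 1L), function(m) bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L))
    }),
    recursive = FALSE
  )
  for (a in seqs) {
    for (b in seqs) {
      expect_identical(lcs_length(a, b), lcs_bruteforce(a, b))
    }
  }
})

test_that("LCS equals enumeration on random mid-length pairs", {
  set.seed(77)
  for (i in 1:60) {
    a <- sample(0:1, sample(6:12, 1), replace = TRUE)
    b <- sample(0:1, sample(6:12, 1), replace = TRUE)
    expect_identical(lcs_length(a, b), lcs_bruteforce(a, b))
  }
})

test_that("LCS obeys symmetry, bounds, and concatenation superadditivity", {
  set.seed(13)
  for (i in 1:100) {
    a <- sample(0:2, sample(1:25, 1), replace = TRUE)
    b <- sample(0:2, sample(1:25, 1), replace = TRUE)
    l <- lcs_length(a, b)
    expect_identical(l, lcs_length(b, a))
    expect_lte(l, min(length(a), length(b)))
    a2 <- sample(0:2, sample(1:15, 1), replace = TRUE)
    b2 <- sample(0:2, sample(1:15, 1), replace = TRUE)
    expect_gte(lcs_length(c(a, a2), c(b, b2)), l + lcs_length(a2, b2))
  }
})

test_that("SMACR is exact on identity and counts failures against an all-ones standard", {
  pair <- generate_pose_pair(n_frames = 9, seed = 8)
  sm <- smacr_score(pair$standard, pair$standard)
  expect_equal(sm$smacr_pct, 100)

  # 5 passing positions among 9: SMACR = 5/9
  std <- make_pose(matrix(90, 9, 1))
  ev_angles <- matrix(90, 9, 1)
  ev_angles[c(2, 4, 6, 9), 1] <- 150  # 60 degrees off -> similarity 0.5
  ev <- make_pose(ev_angles)
  sm2 <- smacr_score(ev, std)
  expect_equal(sm2$smacr_pct, 100 * 5 / 9, tolerance = 1e-9)
  expect_equal(sm2$r_lcs, 5 / 9, tolerance = 1e-12)
})

test_that("SMACR does not depend on beta for equal-length sequences", {
  pair <- generate_pose_pair(n_frames = 30, angle_noise_sd = 18, seed = 10)
  out <- lapply(c(0.5, 1, 2), function(b) {
    smacr_score(pair$evaluated, pair$standard, beta = b)$smacr_pct
  })
  expect_equal(out[[1]], out[[2]])
  expect_equal(out[[2]], out[[3]])
})

test_that("SMACR is monotone when a failing position is repaired", {
  std <- make_pose(matrix(90, 10, 1))
  ev_angles <- matrix(90, 10, 1)
  ev_angles[c(3, 7), 1] <- 160
  base <- smacr_score(make_pose(ev_angles), std)$smacr_pct
  ev_angles[7, 1] <- 90  # flip one 0 token to 1
  repaired <- smacr_score(make_pose(ev_angles), std)$smacr_pct
  expect_gt(repaired, base)
})

test_that("SMACR hits its limiting filters", {
  pair <- generate_pose_pair(n_frames = 20, angle_noise_sd = 25, seed = 14)
  expect_equal(
    smacr_score(pair$evaluated, pair$standard, filter = 1e-9)$smacr_pct, 100
  )
  strict <- smacr_score(pair$evaluated, pair$standard, filter = 1)
  expect_lt(strict$smacr_pct, 100)
})

test_that("per-frame mode binarizes keyframe similarities", {
  std <- make_pose(matrix(c(90, 90, 90, 45, 90, 90, 135, 90), 2, 4))
  ev <- make_pose(matrix(90, 2, 4))
  sm <- smacr_score(ev, std, mode = "per_frame")
  s_frame <- vapply(1:2, function(i) {
    cosine_similarity_seq(angle_matrix(ev)[i, ], angle_matrix(std)[i, ])
  }, numeric(1))
  expect_equal(sm$tokens$similarity, s_frame, tolerance = 1e-12)
  expect_equal(sm$r_lcs, mean(s_frame >= 0.85), tolerance = 1e-12)
})

test_that("evaluate_performance reports both statistics with a config echo", {
  pair <- generate_pose_pair(n_frames = 25, angle_noise_sd = 12, seed = 6)
  ev <- evaluate_performance(pair$evaluated, pair$standard, filter = 0.9, beta = 2)
  expect_lte(ev$ascs_pct, 100)
  expect_lte(ev$smacr_pct, 100)
  expect_equal(ev$config$filter, 0.9)
  expect_equal(ev$config$beta, 2)
  g <- glance(ev)
  expect_equal(g$ascs_pct, ev$ascs_pct)
  expect_equal(g$r_lcs, g$p_lcs)
  expect_equal(g$f_lcs, g$r_lcs, tolerance = 1e-12)
  td <- tidy(ev)
  expect_equal(nrow(td), 8)
  expect_s3_class(autoplot(ev), "ggplot")

  ident <- evaluate_performance(pair$standard, pair$standard)
  expect_equal(ident$ascs_pct, 100)
  expect_equal(ident$smacr_pct, 100)

  mismatched <- make_pose(matrix(90, 3, 2))
  expect_error(evaluate_performance(mismatched, pair$standard),
               class = "danceval_invalid_input")
})

test_that("evaluation JSON report carries scores and configuration", {
  pair <- generate_pose_pair(n_frames = 10, angle_noise_sd = 5, seed = 3)
  ev <- evaluate_performance(pair$evaluated, pair$standard)
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_json(ev, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$ascs_pct, ev$ascs_pct)
  expect_equal(doc$smacr_pct, ev$smacr_pct)
  expect_equal(doc$config$filter, 0.85)
})
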