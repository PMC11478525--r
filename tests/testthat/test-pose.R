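test_that("joint_angle matches the direct arccos oracle on random triples", {
  expect_equal(joint_angle(c(0, 0), c(0, 1), c(0, 2)), 180)
  expect_equal(joint_angle(c(0, 0), c(0, 1), c(1, 1)), 90)
  set.seed(42)
  for (i in 1:200) {
    a <- runif(2, -100, 100); b <- runif(2, -100, 100); c <- runif(2, -100, 100)
    expect_equal(joint_angle(a, b, c), angle_oracle(a, b, c), tolerance = 1e-9)
  }
  expect_error(joint_angle(c(1, 1), c(1, 1), c(0, 0)), class = "danceval_invalid_input")
})

test_that("angles are invariant under similarity transforms of the keypoints", {
  set.seed(9)
  kp <- t_pose_keypoints()
  def <- default_feature_def()
  base <- compute_feature_vector(kp, def)
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.2, 5)
    shift <- runif(2, -50, 50)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy <- s * (as.matrix(kp[, c("x", "y")]) %*% rot) +
      matrix(shift, nrow(kp), 2, byrow = TRUE)
    kp2 <- kp
    kp2$x <- xy[, 1]
    kp2$y <- xy[, 2]
    # acos is ill-conditioned near collinear joints; 1e-6 deg is tight enough
    expect_equal(compute_feature_vector(kp2, def), base, tolerance = 1e-6)
  }
})

test_that("the T-pose has straight elbows and knees, and mirror symmetry holds", {
  kp <- t_pose_keypoints()
  def <- default_feature_def()
  v <- compute_feature_vector(kp, def)
  expect_equal(unname(v[c("elbow_l", "elbow_r", "knee_l", "knee_r")]),
               rep(180, 4), tolerance = 1e-9)
  # mirror the pose across x = 0: left features take the right's values
  kpm <- kp
  kpm$x <- -kp$x
  vm <- compute_feature_vector(kpm, def)
  expect_equal(unname(vm[c("elbow_l", "shoulder_l", "knee_l", "hip_l")]),
               unname(v[c("elbow_r", "shoulder_r", "knee_r", "hip_r")]),
               tolerance = 1e-9)
})

test_that("missing joints make exactly their dependent features absent", {
  kp <- t_pose_keypoints()
  kp$x[kp$joint == "wrist_l"] <- NA
  kp$y[kp$joint == "wrist_l"] <- NA
  v <- compute_feature_vector(kp, default_feature_def())
  expect_true(is.na(v["elbow_l"]))
  expect_false(anyNA(v[setdiff(names(v), "elbow_l")]))
})

test_that("the trunk feature measures inclination from vertical", {
  kp <- t_pose_keypoints()
  def <- default_feature_def(include_trunk = TRUE)
  v <- compute_feature_vector(kp, def)
  # upright T-pose: neck sits straight above the hip midpoint
  expect_equal(unname(v["trunk"]), 0, tolerance = 1e-9)
})

test_that("OpenPose JSON fixtures round-trip with confidence-zero masking", {
  dir <- withr::local_tempdir()
  f0 <- t_pose_keypoints(0L)
  f3 <- t_pose_keypoints(3L)
  f3$confidence[f3$joint == "wrist_l"] <- 0
  paths <- write_openpose_fixture(dir, list(f0, f3))
  kp <- read_keypoint_files(paths)
  expect_equal(sort(unique(kp$frame_index)), c(0L, 3L))
  expect_equal(nrow(kp), 36)
  masked <- kp[kp$frame_index == 3 & kp$joint == "wrist_l", ]
  expect_true(is.na(masked$x))

  bad <- file.path(dir, "trunc_000000000009_keypoints.json")
  writeLines('{"people": [{"pose_keypoints_2d": [1, 2', bad)
  expect_error(read_keypoint_files(bad), class = "danceval_parse_error")
  expect_error(skeleton_layout("halpe26"), class = "danceval_invalid_input")
})

test_that("pose_description aligns frames by index and reports missing ones", {
  frames <- lapply(c(0L, 2L, 4L, 6L), t_pose_keypoints)
  kp <- do.call(rbind, frames)
  kf <- data.frame(beat_time_s = c(0, 0.5, 1.0), frame_index = c(0L, 2L, 6L))
  def <- default_feature_def()
  desc <- pose_description(kp, kf, def)
  expect_equal(dim(angle_matrix(desc)), c(3L, 8L))
  # input row order must not matter: alignment is by frame_index
  desc2 <- pose_description(kp[sample(nrow(kp)), ], kf, def)
  expect_equal(angle_matrix(desc2), angle_matrix(desc))

  err <- tryCatch(
    pose_description(kp, data.frame(beat_time_s = 0, frame_index = 99L), def),
    condition = identity
  )
  expect_s3_class(err, "danceval_missing_frame")
  expect_match(conditionMessage(err), "99")
})

test_that("pose descriptions survive the CSV round trip", {
  pair <- generate_pose_pair(n_frames = 12, angle_noise_sd = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_description(pair$standard, path)
  back <- read_pose_description(path)
  expect_equal(angle_matrix(back), angle_matrix(pair$standard), tolerance = 1e-6)
  expect_equal(back$beat_time_s, pair$standard$beat_time_s)
})

test_that("consolidated keypoint tables validate joints and mask zero confidence", {
  kp <- t_pose_keypoints()
  kp$confidence[1] <- 0
  tab <- read_keypoint_table(kp)
  expect_true(is.na(tab$x[1]))
  kp_bad <- kp
  kp_bad$joint[2] <- "tail"
  expect_error(read_keypoint_table(kp_bad), class = "danceval_invalid_input")
})
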