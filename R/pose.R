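#' Skeleton layouts
#'
#' Joint naming for the two common output layouts of 2-D pose estimators:
#' the 18-joint COCO-style skeleton and the 25-joint body layout (which has
#' an explicit `mid_hip`). Order matches the flat keypoint triples in the
#' estimator's JSON output.
#'
#' @param name `"coco18"` or `"body25"`.
#' @return Character vector of joint names in layout order.
#' @export
skeleton_layout <- function(name = c("coco18", "body25")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop_invalid(paste0("Unknown skeleton layout: ", paste(name, collapse = ", ")))
  })
  switch(name,
    coco18 = c(
      "nose", "neck",
      "shoulder_r", "elbow_r", "wrist_r",
      "shoulder_l", "elbow_l", "wrist_l",
      "hip_r", "knee_r", "ankle_r",
      "hip_l", "knee_l", "ankle_l",
      "eye_r", "eye_l", "ear_r", "ear_l"
    ),
    body25 = c(
      "nose", "neck",
      "shoulder_r", "elbow_r", "wrist_r",
      "shoulder_l", "elbow_l", "wrist_l",
      "mid_hip",
      "hip_r", "knee_r", "ankle_r",
      "hip_l", "knee_l", "ankle_l",
      "eye_r", "eye_l", "ear_r", "ear_l",
      "big_toe_l", "small_toe_l", "heel_l",
      "big_toe_r", "small_toe_r", "heel_r"
    )
  )
}

#' Default joint-angle feature definition
#'
#' Eight goniometric angles covering the limbs that drive dance scoring —
#' upper arms, forearms, thighs, calves — measured at the middle joint of
#' each triple: left/right elbow (shoulder-elbow-wrist), shoulder
#' (hip-shoulder-elbow), knee (hip-knee-ankle), and hip
#' (shoulder-hip-knee). Optionally a ninth trunk feature: the inclination
#' of the neck-to-mid-hip segment from vertical. Fully overridable — any
#' tibble with columns `name`, `joint_a`, `joint_b`, `joint_c`, `type`
#' (`"triplet"` or `"trunk"`) works.
#'
#' @param layout Skeleton layout name; `mid_hip` is derived as the hip
#'   midpoint where the layout lacks it.
#' @param include_trunk Add the trunk-inclination feature?
#' @return A tibble feature definition (class `angle_feature_def`).
#' @export
default_feature_def <- function(layout = "coco18", include_trunk = FALSE) {
  joints <- skeleton_layout(layout)
  def <- tibble(
    name = c(
      "elbow_l", "elbow_r", "shoulder_l", "shoulder_r",
      "knee_l", "knee_r", "hip_l", "hip_r"
    ),
    joint_a = c(
      "shoulder_l", "shoulder_r", "hip_l", "hip_r",
      "hip_l", "hip_r", "shoulder_l", "shoulder_r"
    ),
    joint_b = c(
      "elbow_l", "elbow_r", "shoulder_l", "shoulder_r",
      "knee_l", "knee_r", "hip_l", "hip_r"
    ),
    joint_c = c(
      "wrist_l", "wrist_r", "elbow_l", "elbow_r",
      "ankle_l", "ankle_r", "knee_l", "knee_r"
    ),
    type = "triplet"
  )
  if (include_trunk) {
    def <- dplyr::bind_rows(def, tibble(
      name = "trunk", joint_a = "neck", joint_b = "mid_hip",
      joint_c = NA_character_, type = "trunk"
    ))
  }
  validate_feature_def(def, joints)
  attr(def, "layout") <- layout
  class(def) <- c("angle_feature_def", class(def))
  def
}

validate_feature_def <- function(def, joints) {
  needed <- c("name", "joint_a", "joint_b", "joint_c", "type")
  if (!all(needed %in% names(def))) {
    stop_invalid("Feature definition needs columns name, joint_a, joint_b, joint_c, type.")
  }
  if (anyDuplicated(def$name)) stop_invalid("Feature names must be unique.")
  used <- setdiff(
    stats::na.omit(c(def$joint_a, def$joint_b, def$joint_c)),
    c(joints, "mid_hip")
  )
  if (length(used)) {
    stop_invalid(paste0("Unknown joints in feature definition: ", paste(used, collapse = ", ")))
  }
  invisible(def)
}

#' Read per-frame keypoint JSON files
#'
#' Parses the flat-triple `people[].pose_keypoints_2d` layout (one JSON
#' document per frame). When several people are detected, the one with the
#' highest mean keypoint confidence is kept (a single dancer is assumed).
#' Keypoints with zero confidence are marked missing (`NA` coordinates).
#' Frame indices are taken from the last run of digits in each file name
#' (the estimator's `<prefix>_<%012d>_keypoints.json` convention), falling
#' back to file order.
#'
#' @param paths Character vector of JSON file paths.
#' @param layout Skeleton layout name.
#' @return A tibble with columns `frame_index`, `joint`, `x`, `y`,
#'   `confidence` — one row per joint per frame.
#' @export
read_keypoint_files <- function(paths, layout = "coco18") {
  joints <- skeleton_layout(layout)
  rows <- purrr::imap(paths, function(path, i) {
    doc <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop_parse(paste0("Cannot parse keypoint file ", path, ": ", conditionMessage(e)))
    )
    people <- doc$people
    if (is.null(people) || length(people) == 0L) {
      stop_parse(paste0("No `people` entry in keypoint file ", path))
    }
    kp_list <- purrr::map(people, function(p) {
      v <- unlist(p$pose_keypoints_2d)
      if (is.null(v) || length(v) != 3L * length(joints)) {
        stop_parse(sprintf(
          "Keypoint file %s: expected %d values for layout with %d joints.",
          path, 3L * length(joints), length(joints)
        ))
      }
      matrix(v, ncol = 3, byrow = TRUE)
    })
    conf <- vapply(kp_list, function(m) mean(m[, 3]), numeric(1))
    m <- kp_list[[which.max(conf)]]
    digits <- regmatches(basename(path), gregexpr("[0-9]+", basename(path)))[[1]]
    fidx <- if (length(digits)) as.integer(digits[length(digits)]) else i - 1L
    tibble(
      frame_index = fidx,
      joint = joints,
      x = ifelse(m[, 3] > 0, m[, 1], NA_real_),
      y = ifelse(m[, 3] > 0, m[, 2], NA_real_),
      confidence = m[, 3]
    )
  })
  dplyr::bind_rows(rows)
}

#' Read a consolidated keypoint table
#'
#' Accepts a CSV path or data frame with columns `frame_index, joint, x, y,
#' confidence`; zero-confidence keypoints are marked missing.
#'
#' @param x CSV path or data frame.
#' @param layout Skeleton layout the joint names must belong to.
#' @return A tibble in the same shape as [read_keypoint_files()].
#' @export
read_keypoint_table <- function(x, layout = "coco18") {
  joints <- skeleton_layout(layout)
  df <- if (is.character(x)) {
    tryCatch(
      utils::read.csv(x, stringsAsFactors = FALSE),
      error = function(e) stop_parse(paste0("Cannot read keypoint table ", x, ": ", conditionMessage(e)))
    )
  } else {
    as.data.frame(x)
  }
  needed <- c("frame_index", "joint", "x", "y", "confidence")
  if (!all(needed %in% names(df))) {
    stop_parse("Keypoint table needs columns frame_index, joint, x, y, confidence.")
  }
  bad <- setdiff(unique(df$joint), joints)
  if (length(bad)) {
    stop_invalid(paste0("Joints not in layout '", layout, "': ", paste(bad, collapse = ", ")))
  }
  out <- as_tibble(df[needed])
  out$x[out$confidence <= 0] <- NA_real_
  out$y[out$confidence <= 0] <- NA_real_
  out
}

#' Interior angle at a joint
#'
#' Angle in degrees at vertex `b` between rays `b->a` and `b->c`, in
#' \[0, 180\]. Invariant under translation, rotation, and uniform scaling of
#' the coordinates (so image resolution and the y-down convention do not
#' matter).
#'
#' @param a,b,c Length-2 numeric coordinates (pixels).
#' @return Angle in degrees.
#' @examples
#' joint_angle(c(0, 0), c(0, 1), c(1, 1))  # 90
#' @export
joint_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (!all(is.finite(c(u, v))) || nu == 0 || nv == 0) {
    stop_invalid("Coincident or non-finite points: angle undefined.")
  }
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Compute one frame's angle feature vector
#'
#' One angle per feature row; `NA` (absent) wherever any required joint is
#' missing in the frame. Trunk-type features measure the inclination of the
#' `joint_a -> joint_b` segment from the image vertical.
#'
#' @param frame_keypoints Keypoint tibble rows for a single frame.
#' @param def An `angle_feature_def`.
#' @return Named numeric vector of length `nrow(def)`, degrees in
#'   \[0, 180\] or `NA`.
#' @export
compute_feature_vector <- function(frame_keypoints, def) {
  kp <- frame_keypoints
  lookup <- function(j) {
    if (j == "mid_hip" && !j %in% kp$joint) {
      l <- lookup("hip_l"); r <- lookup("hip_r")
      return((l + r) / 2)
    }
    row <- which(kp$joint == j)
    if (length(row) != 1L) return(c(NA_real_, NA_real_))
    c(kp$x[row[1]], kp$y[row[1]])
  }
  out <- vapply(seq_len(nrow(def)), function(i) {
    a <- lookup(def$joint_a[i])
    b <- lookup(def$joint_b[i])
    if (def$type[i] == "trunk") {
      seg <- a - b  # mid_hip -> neck
      if (!all(is.finite(seg)) || sum(seg^2) == 0) return(NA_real_)
      # vertical reference: up is -y in image coordinates
      return(joint_angle(b + seg, b, b + c(0, -1) * sqrt(sum(seg^2))))
    }
    cc <- lookup(def$joint_c[i])
    if (!all(is.finite(c(a, b, cc)))) return(NA_real_)
    joint_angle(a, b, cc)
  }, numeric(1))
  setNames(out, def$name)
}

#' Build a pose description sequence over keyframes
#'
#' Assembles the n-keyframes-by-m-features angle matrix that quantifies a
#' performance: for each keyframe index, the corresponding frame's
#' keypoints are reduced to the angle features of `def`. The same routine
#' serves the reference and the evaluated performance.
#'
#' @param keypoints Keypoint tibble (from [read_keypoint_files()] or
#'   [read_keypoint_table()]).
#' @param keyframes A `keyframe_sequence` (or data frame with
#'   `frame_index` and `beat_time_s`).
#' @param def An `angle_feature_def`.
#' @return A tibble of class `pose_description`: `beat_time_s`,
#'   `frame_index`, then one column per feature (degrees, `NA` = absent);
#'   attribute `feature_def`.
#' @export
pose_description <- function(keypoints, keyframes, def = default_feature_def()) {
  missing_idx <- setdiff(keyframes$frame_index, unique(keypoints$frame_index))
  if (length(missing_idx)) {
    abort(
      paste0(
        "No pose data for keyframe indices: ",
        paste(missing_idx, collapse = ", ")
      ),
      class = c("danceval_missing_frame", "danceval_error")
    )
  }
  rows <- purrr::map(keyframes$frame_index, function(fi) {
    compute_feature_vector(keypoints[keypoints$frame_index == fi, , drop = FALSE], def)
  })
  angles <- do.call(rbind, rows)
  as_pose_description(angles, keyframes$beat_time_s, def,
                      frame_index = keyframes$frame_index)
}

#' Construct a pose description from an angle matrix
#'
#' @param angles n x m numeric matrix of angles in degrees (`NA` = absent);
#'   columns ordered as `def$name`.
#' @param beat_times Beat time of each row in seconds.
#' @param def An `angle_feature_def` (or anything with a `name` column).
#' @param frame_index Optional source frame indices.
#' @return A `pose_description` tibble.
#' @export
as_pose_description <- function(angles, beat_times, def = default_feature_def(),
                                frame_index = NULL) {
  angles <- as.matrix(angles)
  if (nrow(angles) != length(beat_times)) {
    stop_invalid("`angles` rows and `beat_times` lengths differ.")
  }
  present <- angles[is.finite(angles)]
  if (length(present) && (any(present < 0) || any(present > 180))) {
    stop_invalid("Angles must lie in [0, 180] degrees.")
  }
  colnames(angles) <- def$name
  out <- dplyr::bind_cols(
    tibble(
      beat_time_s = beat_times,
      frame_index = frame_index %||% NA_integer_
    ),
    as_tibble(angles)
  )
  attr(out, "feature_def") <- def
  class(out) <- c("pose_description", class(out))
  out
}

#' Extract the angle matrix of a pose description
#'
#' @param x A `pose_description`.
#' @return The n x m numeric angle matrix.
#' @export
angle_matrix <- function(x) {
  def <- attr(x, "feature_def")
  as.matrix(x[, def$name, drop = FALSE])
}

#' Write a pose description as CSV
#'
#' Header: `beat_time_s, <feature names...>`.
#'
#' @param x A `pose_description`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_description <- function(x, path) {
  def <- attr(x, "feature_def")
  utils::write.csv(
    as.data.frame(x[, c("beat_time_s", def$name)]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a pose description CSV
#'
#' @param path CSV written by [write_pose_description()].
#' @return A `pose_description`.
#' @export
read_pose_description <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_parse(paste0("Cannot read pose description ", path))
  )
  if (!"beat_time_s" %in% names(df)) {
    stop_parse(paste0("Missing beat_time_s column in ", path))
  }
  feat <- setdiff(names(df), c("beat_time_s", "frame_index"))
  def <- tibble(
    name = feat, joint_a = NA_character_, joint_b = NA_character_,
    joint_c = NA_character_, type = "triplet"
  )
  as_pose_description(as.matrix(df[feat]), df$beat_time_s, def)
}
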