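# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration and direct formulas only.

# LCS by exhaustive subsequence enumeration: every subsequence of `a`
# (bitmask order), checked for being a subsequence of `b`.
lcs_bruteforce <- function(a, b) {
  if (length(a) > length(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  na <- length(a)
  best <- 0L
  is_subseq <- function(s, t) {
    if (length(s) == 0L) return(TRUE)
    j <- 1L
    for (x in t) {
      if (isTRUE(x == s[j])) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  for (mask in 0:(2^na - 1L)) {
    picked <- a[bitwAnd(bitwShiftR(mask, 0:(na - 1L)), 1L) == 1L]
    if (length(picked) > best && is_subseq(picked, b)) {
      best <- length(picked)
    }
  }
  best
}

# LCS via Biostrings global alignment: match = 1, mismatch = 0, gaps free.
lcs_biostrings <- function(a, b) {
  letters_of <- function(x) paste(c("A", "B", "C")[x + 1L], collapse = "")
  mat <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(mat) <- 1
  as.integer(Biostrings::pairwiseAlignment(
    letters_of(a), letters_of(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0, scoreOnly = TRUE
  ))
}

# Exhaustive beat-chain enumeration for the DP optimality check. Chains
# start at any frame with no admissible predecessor (index <= dmin), step
# by gaps d with d * hop in [lo * tau_p, hi * tau_p], and are scored by the
# summed onset strength plus omega-weighted log-interval penalties. The
# optimum is taken over chains whose last beat lies in the final tau_p.
best_chain_bruteforce <- function(o, hop, tau_p, omega, lo = 0.5, hi = 2.0) {
  n <- length(o)
  dmin <- max(1L, ceiling(lo * tau_p / hop - 1e-9))
  dmax <- max(dmin, floor(hi * tau_p / hop + 1e-9))
  tail_start <- n - min(n, max(1L, floor(tau_p / hop))) + 1L
  best <- -Inf
  dfs <- function(k, score) {
    if (k >= tail_start && score > best) best <<- score
    for (d in dmin:dmax) {
      nxt <- k + d
      if (nxt > n) break
      pen <- -omega * (log(d * hop / tau_p))^2
      dfs(nxt, score + o[nxt] + pen)
    }
  }
  for (s in seq_len(min(dmin, n))) dfs(s, o[s])
  best
}

# Direct cosine of the interior angle at b, by the normalized dot product.
angle_oracle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# Minimal feature definition for hand-built angle matrices.
bare_feature_def <- function(names) {
  tibble::tibble(
    name = names,
    joint_a = NA_character_, joint_b = NA_character_,
    joint_c = NA_character_, type = "triplet"
  )
}

make_pose <- function(angles, names = paste0("f", seq_len(ncol(angles)))) {
  as_pose_description(
    angles,
    beat_times = (seq_len(nrow(angles)) - 1) * 0.5,
    def = bare_feature_def(names)
  )
}

# T-pose keypoint coordinates on the 18-joint layout: arms straight out
# along the horizontal, legs vertical. y grows downward (image convention).
t_pose_keypoints <- function(frame_index = 0L) {
  coords <- list(
    nose = c(0, -20), neck = c(0, 0),
    shoulder_r = c(-30, 0), elbow_r = c(-60, 0), wrist_r = c(-90, 0),
    shoulder_l = c(30, 0), elbow_l = c(60, 0), wrist_l = c(90, 0),
    hip_r = c(-15, 60), knee_r = c(-15, 110), ankle_r = c(-15, 160),
    hip_l = c(15, 60), knee_l = c(15, 110), ankle_l = c(15, 160),
    eye_r = c(-5, -25), eye_l = c(5, -25), ear_r = c(-10, -22), ear_l = c(10, -22)
  )
  tibble::tibble(
    frame_index = frame_index,
    joint = names(coords),
    x = vapply(coords, `[`, numeric(1), 1),
    y = vapply(coords, `[`, numeric(1), 2),
    confidence = 0.9
  )
}

# Writes one OpenPose-style JSON keypoint file per frame; returns paths.
write_openpose_fixture <- function(dir, frames) {
  paths <- character(0)
  for (i in seq_along(frames)) {
    kp <- frames[[i]]
    flat <- as.vector(t(as.matrix(kp[, c("x", "y", "confidence")])))
    doc <- list(
      version = 1.3,
      people = list(list(pose_keypoints_2d = flat))
    )
    p <- file.path(dir, sprintf("fixture_%012d_keypoints.json", kp$frame_index[1]))
    jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  paths
}
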