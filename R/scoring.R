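#' Cosine similarity of two value sequences
#'
#' `s = (q . theta) / (||q|| ||theta||)` after pairwise deletion of
#' positions where either entry is absent (`NA`). For nonnegative data
#' (joint angles) the result lies in \[0, 1\].
#'
#' @param q,theta Equal-length numeric sequences.
#' @param min_pairs Minimum retained positions after pairwise deletion
#'   (default 2).
#' @return Similarity in \[-1, 1\] (\[0, 1\] for nonnegative input).
#' @examples
#' cosine_similarity_seq(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosine_similarity_seq <- function(q, theta, min_pairs = 2) {
  if (length(q) != length(theta) || length(q) == 0L) {
    stop_invalid("`q` and `theta` must have equal nonzero length.")
  }
  ok <- is.finite(q) & is.finite(theta)
  if (!any(ok)) {
    stop_insufficient("All positions absent; similarity undefined.")
  }
  if (sum(ok) < min_pairs) {
    stop_insufficient(sprintf(
      "Only %d retained position(s) after pairwise deletion; need >= %d.",
      sum(ok), min_pairs
    ))
  }
  qq <- q[ok]
  tt <- theta[ok]
  nq <- sqrt(sum(qq^2))
  nt <- sqrt(sum(tt^2))
  if (nq == 0 || nt == 0) {
    abort("Zero-norm sequence; cosine similarity undefined.",
          class = c("danceval_undefined_similarity", "danceval_error"))
  }
  sum(qq * tt) / (nq * nt)
}

#' ASCS: average cosine similarity of action feature sequences
#'
#' For each feature `j`, the cosine similarity between the evaluated and
#' the standard angle sequence over the n keyframes (`s_j`); the overall
#' static-accuracy score is the mean of the `s_j`, reported as a
#' percentage. Per-keyframe similarities `s_i` (cosine of the two m-feature
#' row vectors) are computed alongside for diagnostics and for the
#' per-frame continuity mode.
#'
#' @param evaluated,standard `pose_description` objects with identical
#'   shape and feature names.
#' @param min_pairs Passed to [cosine_similarity_seq()].
#' @return A `similarity_breakdown`: `s_per_feature` (named), `s_per_frame`,
#'   `mean_score` (fraction), `ascs_pct`.
#' @export
ascs_score <- function(evaluated, standard, min_pairs = 2) {
  q <- angle_matrix(evaluated)
  th <- angle_matrix(standard)
  check_same_shape(q, th)
  s_feat <- vapply(
    seq_len(ncol(q)),
    function(j) cosine_similarity_seq(q[, j], th[, j], min_pairs),
    numeric(1)
  )
  names(s_feat) <- colnames(q)
  s_frame <- vapply(
    seq_len(nrow(q)),
    function(i) cosine_similarity_seq(q[i, ], th[i, ], min_pairs),
    numeric(1)
  )
  structure(
    list(
      s_per_feature = s_feat,
      s_per_frame = s_frame,
      mean_score = mean(s_feat),
      ascs_pct = 100 * mean(s_feat)
    ),
    class = "similarity_breakdown"
  )
}

check_same_shape <- function(q, th) {
  if (!all(dim(q) == dim(th))) {
    stop_invalid(sprintf(
      "Shape mismatch: evaluated %dx%d vs standard %dx%d.",
      nrow(q), ncol(q), nrow(th), ncol(th)
    ))
  }
  if (!identical(colnames(q), colnames(th))) {
    stop_invalid("Feature definitions differ between the two sequences.")
  }
  invisible(TRUE)
}

#' @export
print.similarity_breakdown <- function(x, ...) {
  cat(sprintf("<similarity_breakdown: ASCS %.1f%% over %d features, %d frames>\n",
              x$ascs_pct, length(x$s_per_feature), length(x$s_per_frame)))
  invisible(x)
}

#' Threshold-filter similarity scores into a 0/1 sequence
#'
#' Token is 1 when the score reaches the filter (inclusive boundary: a
#' score exactly at the threshold counts as acceptable).
#'
#' @param scores Similarities in \[0, 1\] (`NA` allowed, propagated).
#' @param filter Threshold in (0, 1\] (default 0.85).
#' @return Integer vector of 0/1 tokens with attribute `threshold_used`.
#' @export
binarize_scores <- function(scores, filter = 0.85) {
  if (!(filter > 0 && filter <= 1)) stop_invalid("`filter` must lie in (0, 1].")
  sc <- scores[is.finite(scores)]
  if (length(sc) && (any(sc < -1e-9) || any(sc > 1 + 1e-9))) {
    stop_invalid("`scores` must lie in [0, 1].")
  }
  out <- as.integer(scores >= filter)
  attr(out, "threshold_used") <- filter
  out
}

#' Longest common subsequence length
#'
#' Classic O(|a| |b|) dynamic programme over token sequences of any
#' alphabet. Empty input gives 0.
#'
#' @param a,b Token vectors (numeric, integer, or character).
#' @return Integer LCS length.
#' @examples
#' lcs_length(c(1, 0, 1, 0, 1), c(1, 1, 1, 1, 1))  # 3
#' @export
lcs_length <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    curr <- integer(nb + 1L)
    ai <- a[i]
    for (j in seq_len(nb)) {
      curr[j + 1L] <- if (isTRUE(ai == b[j])) {
        prev[j] + 1L
      } else {
        max(prev[j + 1L], curr[j])
      }
    }
    prev <- curr
  }
  prev[nb + 1L]
}

# Per-position similarity of two scalar angles: cosine of the angular
# difference of the two limb directions, clamped to [0, 1].
angle_pair_similarity <- function(q, th) {
  s <- cos((q - th) * pi / 180)
  pmax(0, s)
}

#' SMACR: continuity score over threshold-filtered similarity sequences
#'
#' Per-position similarities are binarized with `filter` and compared
#' against the standard's own tokens (all ones by construction) through the
#' longest common subsequence: `R_LCS = P_LCS = LCS / n`, combined as
#' `F_LCS = (1 + beta^2) R P / (R + beta^2 P)` — which collapses to `R_LCS`
#' at equal lengths, independent of `beta`.
#'
#' Two token constructions are available. `per_feature` (default) builds,
#' for each feature `j`, a length-n 0/1 sequence from the per-position
#' angular similarities (cosine of the angle difference) and averages the
#' per-feature `F_LCS`. `per_frame` binarizes the n per-keyframe cosine
#' similarities of the full feature vectors into a single sequence.
#'
#' @param evaluated,standard `pose_description` objects, same shape.
#' @param filter Similarity threshold in (0, 1\] (default 0.85).
#' @param beta F-score weight (default 1); has no effect at equal lengths.
#' @param mode `"per_feature"` or `"per_frame"`.
#' @param min_pairs Minimum retained positions per sequence.
#' @return A list: `smacr_pct`, `r_lcs`, `p_lcs`, `f_lcs`, `per_feature`
#'   tibble (feature, n_used, pass_rate, f_lcs), `tokens` (per_frame mode),
#'   `mode`, `filter`, `beta`.
#' @export
smacr_score <- function(evaluated, standard, filter = 0.85, beta = 1,
                        mode = c("per_feature", "per_frame"), min_pairs = 2) {
  mode <- match.arg(mode)
  if (beta <= 0) stop_invalid("`beta` must be positive.")
  q <- angle_matrix(evaluated)
  th <- angle_matrix(standard)
  check_same_shape(q, th)

  f_of <- function(r, p) {
    if (r + p == 0) return(0)
    (1 + beta^2) * r * p / (r + beta^2 * p)
  }

  if (mode == "per_feature") {
    per <- purrr::map(seq_len(ncol(q)), function(j) {
      ok <- is.finite(q[, j]) & is.finite(th[, j])
      if (sum(ok) < min_pairs) {
        stop_insufficient(sprintf(
          "Feature '%s': only %d usable position(s).", colnames(q)[j], sum(ok)
        ))
      }
      s <- angle_pair_similarity(q[ok, j], th[ok, j])
      tok <- binarize_scores(s, filter)
      n <- length(tok)
      r <- lcs_length(tok, rep(1L, n)) / n
      tibble(
        feature = colnames(q)[j],
        n_used = n,
        pass_rate = mean(tok),
        similarity_mean = mean(s),
        r_lcs = r,
        f_lcs = f_of(r, r)
      )
    })
    per <- dplyr::bind_rows(per)
    list(
      smacr_pct = 100 * mean(per$f_lcs),
      r_lcs = mean(per$r_lcs),
      p_lcs = mean(per$r_lcs),
      f_lcs = mean(per$f_lcs),
      per_feature = per,
      tokens = NULL,
      mode = mode, filter = filter, beta = beta
    )
  } else {
    s_frame <- vapply(
      seq_len(nrow(q)),
      function(i) cosine_similarity_seq(q[i, ], th[i, ], min_pairs),
      numeric(1)
    )
    tok <- binarize_scores(s_frame, filter)
    n <- length(tok)
    r <- lcs_length(tok, rep(1L, n)) / n
    f <- f_of(r, r)
    list(
      smacr_pct = 100 * f,
      r_lcs = r,
      p_lcs = r,
      f_lcs = f,
      per_feature = NULL,
      tokens = tibble(frame = seq_len(n), similarity = s_frame, token = as.integer(tok)),
      mode = mode, filter = filter, beta = beta
    )
  }
}

#' Evaluate a performance against a standard
#'
#' Single entry point combining static accuracy (ASCS, [ascs_score()]) and
#' movement continuity (SMACR, [smacr_score()]) into one report.
#'
#' @inheritParams smacr_score
#' @return A `dance_evaluation` object; see [tidy.dance_evaluation()] and
#'   [glance.dance_evaluation()].
#' @examples
#' pair <- generate_pose_pair(n_frames = 24, angle_noise_sd = 10, seed = 1)
#' ev <- evaluate_performance(pair$evaluated, pair$standard)
#' glance(ev)
#' @export
evaluate_performance <- function(evaluated, standard, filter = 0.85, beta = 1,
                                 mode = c("per_feature", "per_frame"),
                                 min_pairs = 2) {
  mode <- match.arg(mode)
  br <- ascs_score(evaluated, standard, min_pairs)
  sm <- smacr_score(evaluated, standard, filter, beta, mode, min_pairs)
  per_frame <- tibble(
    frame = seq_along(br$s_per_frame),
    beat_time_s = evaluated$beat_time_s,
    similarity = br$s_per_frame,
    token = as.integer(binarize_scores(br$s_per_frame, filter))
  )
  per_feature <- tibble(
    feature = names(br$s_per_feature),
    cosine_similarity = unname(br$s_per_feature)
  )
  if (!is.null(sm$per_feature)) {
    per_feature <- dplyr::left_join(per_feature, sm$per_feature, by = "feature")
  }
  structure(
    list(
      ascs_pct = br$ascs_pct,
      smacr_pct = sm$smacr_pct,
      r_lcs = sm$r_lcs,
      p_lcs = sm$p_lcs,
      f_lcs = sm$f_lcs,
      breakdown = br,
      per_feature = per_feature,
      per_frame = per_frame,
      config = list(filter = filter, beta = beta, mode = mode, min_pairs = min_pairs),
      n_frames = nrow(evaluated),
      n_features = length(br$s_per_feature)
    ),
    class = "dance_evaluation"
  )
}

#' @export
print.dance_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Dance performance evaluation (%d keyframes, %d features)\n",
      "  ASCS  (static accuracy):     %5.1f%%\n",
      "  SMACR (movement continuity): %5.1f%%\n",
      "  filter = %.2f, beta = %g, mode = %s\n"
    ),
    x$n_frames, x$n_features, x$ascs_pct, x$smacr_pct,
    x$config$filter, x$config$beta, x$config$mode
  ))
  invisible(x)
}

#' Tidy a dance evaluation
#'
#' @param x A `dance_evaluation`.
#' @param ... Unused.
#' @return Per-feature tibble: cosine similarity and (in per-feature mode)
#'   pass rate and `F_LCS`.
#' @export
tidy.dance_evaluation <- function(x, ...) {
  x$per_feature
}

#' One-row summary of a dance evaluation
#'
#' @param x A `dance_evaluation`.
#' @param ... Unused.
#' @return Tibble with `ascs_pct`, `smacr_pct`, `r_lcs`, `p_lcs`, `f_lcs`,
#'   sizes, and the configuration echo.
#' @export
glance.dance_evaluation <- function(x, ...) {
  tibble(
    ascs_pct = x$ascs_pct,
    smacr_pct = x$smacr_pct,
    r_lcs = x$r_lcs,
    p_lcs = x$p_lcs,
    f_lcs = x$f_lcs,
    n_frames = x$n_frames,
    n_features = x$n_features,
    filter = x$config$filter,
    beta = x$config$beta,
    mode = x$config$mode
  )
}

#' Plot per-keyframe similarity with the acceptance threshold
#'
#' @param object A `dance_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dance_evaluation <- function(object, ...) {
  ggplot2::ggplot(
    object$per_frame,
    ggplot2::aes(x = .data$beat_time_s, y = .data$similarity)
  ) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$token))) +
    ggplot2::geom_hline(yintercept = object$config$filter, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`0` = "firebrick", `1` = "forestgreen"),
      name = "passes filter"
    ) +
    ggplot2::labs(
      x = "beat time (s)", y = "keyframe similarity",
      title = sprintf("ASCS %.1f%% / SMACR %.1f%%", object$ascs_pct, object$smacr_pct)
    )
}

#' Write an evaluation report as JSON
#'
#' @param x A `dance_evaluation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(x, path) {
  doc <- list(
    ascs_pct = x$ascs_pct,
    smacr_pct = x$smacr_pct,
    r_lcs = x$r_lcs,
    p_lcs = x$p_lcs,
    f_lcs = x$f_lcs,
    per_feature = x$per_feature,
    per_frame = x$per_frame,
    config = x$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
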