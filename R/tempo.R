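#' Beat-interval transition cost
#'
#' Squared error on the log ratio of an observed inter-beat interval to the
#' ideal tempo period: `F = -(log(delta_t / tau_p))^2`. Zero exactly when
#' the interval equals the period, increasingly negative as the ratio moves
#' away from one (symmetrically in log space, so halving and doubling cost
#' the same). Natural logarithm; any other base only rescales the cost and
#' is absorbed by the tracker weight `omega`.
#'
#' @param delta_t Observed interval(s) in seconds (positive).
#' @param tau_p Ideal tempo period in seconds (positive).
#' @return Numeric cost(s), always `<= 0`.
#' @examples
#' transition_cost(0.5, 0.5)   # 0
#' transition_cost(1.0, 0.5)   # -(log 2)^2
#' @export
transition_cost <- function(delta_t, tau_p) {
  if (any(!is.finite(delta_t)) || any(delta_t <= 0)) {
    stop_invalid("`delta_t` must be positive and finite.")
  }
  if (any(!is.finite(tau_p)) || any(tau_p <= 0)) {
    stop_invalid("`tau_p` must be positive and finite.")
  }
  -(log(delta_t / tau_p))^2
}

#' Perceptual tempo weighting
#'
#' Gaussian window on the log2 (octave) axis, centred at the preferred
#' period `tau0`: `W = exp(-0.5 * (log2(tau / tau0) / sigma_oct)^2)`.
#' Equals one at `tau0` (0.5 s, i.e. 120 BPM, by default) and is symmetric
#' in octaves: the period one octave above and one octave below weigh the
#' same.
#'
#' @param tau Candidate period(s) in seconds (positive).
#' @param tau0 Centre of the period preference in seconds.
#' @param sigma_oct Width of the weighting in octaves.
#' @return Weight(s) in (0, 1].
#' @export
tempo_weight <- function(tau, tau0 = 0.5, sigma_oct = 1.0) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop_invalid("`tau` must be positive and finite.")
  }
  if (tau0 <= 0 || sigma_oct <= 0) {
    stop_invalid("`tau0` and `sigma_oct` must be positive.")
  }
  exp(-0.5 * (log2(tau / tau0) / sigma_oct)^2)
}

#' Estimate the global tempo period
#'
#' Computes the tempo period strength `TPS(tau) = W(tau) * sum_t O(t) O(t - tau)`
#' over a discrete lag grid: the raw autocorrelation of the onset envelope,
#' weighted by the perceptual prior [tempo_weight()]. The period estimate is
#' the lag maximising TPS; exact ties break toward the lag closest to
#' `tau0`.
#'
#' @param env An `onset_envelope`.
#' @param tau0,sigma_oct Prior parameters, see [tempo_weight()].
#' @param lag_range Two-element numeric, the searched period range in
#'   seconds (default 0.2-2.0 s, i.e. 30-300 BPM).
#' @return A `tempo_estimate`: fields `tau_p` (s), `bpm`, and `tps` (a
#'   tibble of `lag_s`, `acf`, `weight`, `tps`).
#' @export
estimate_tempo <- function(env, tau0 = 0.5, sigma_oct = 1.0,
                           lag_range = c(0.2, 2.0)) {
  if (!inherits(env, "onset_envelope")) stop_invalid("`env` must be an onset_envelope.")
  if (length(lag_range) != 2L || lag_range[1] <= 0 || lag_range[2] <= lag_range[1]) {
    stop_invalid("`lag_range` must be an increasing positive pair.")
  }
  o <- env$values
  hop <- env$hop_seconds
  n <- length(o)
  lmin <- max(1L, round(lag_range[1] / hop))
  lmax <- round(lag_range[2] / hop)
  if (n < 2L * lmax) {
    stop_insufficient(sprintf(
      "Envelope too short for lag search: %d frames, need >= %d.", n, 2L * lmax
    ))
  }
  if (sd(o) == 0) stop_degenerate("Flat envelope; tempo undefined.")
  lags <- lmin:lmax
  acf_raw <- vapply(
    lags,
    function(l) sum(o[(l + 1L):n] * o[seq_len(n - l)]),
    numeric(1)
  )
  lag_s <- lags * hop
  w <- tempo_weight(lag_s, tau0, sigma_oct)
  tps <- w * acf_raw
  best <- which(tps == max(tps))
  if (length(best) > 1L) {
    best <- best[which.min(abs(lag_s[best] - tau0))]
  }
  structure(
    list(
      tau_p = lag_s[best],
      bpm = 60 / lag_s[best],
      tps = tibble(lag_s = lag_s, acf = acf_raw, weight = w, tps = tps),
      prior = list(tau0 = tau0, sigma_oct = sigma_oct),
      lag_range = lag_range,
      hop_seconds = hop
    ),
    class = "tempo_estimate"
  )
}

#' @export
print.tempo_estimate <- function(x, ...) {
  cat(sprintf(
    "<tempo_estimate: tau_p = %.4f s (%.1f BPM), %d lags searched>\n",
    x$tau_p, x$bpm, nrow(x$tps)
  ))
  invisible(x)
}

#' @rdname estimate_tempo
#' @param x A `tempo_estimate`.
#' @param ... Unused.
#' @export
tidy.tempo_estimate <- function(x, ...) {
  x$tps
}

#' @rdname estimate_tempo
#' @export
glance.tempo_estimate <- function(x, ...) {
  tibble(
    tau_p_s = x$tau_p,
    bpm = x$bpm,
    tau0_s = x$prior$tau0,
    sigma_oct = x$prior$sigma_oct,
    n_lags = nrow(x$tps)
  )
}

#' @rdname estimate_tempo
#' @param object A `tempo_estimate`.
#' @export
autoplot.tempo_estimate <- function(object, ...) {
  ggplot2::ggplot(object$tps, ggplot2::aes(x = .data$lag_s, y = .data$tps)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tau_p, linetype = "dashed") +
    ggplot2::labs(
      x = "candidate period (s)",
      y = "tempo period strength",
      title = sprintf("Tempo period %.3f s (%.1f BPM)", object$tau_p, object$bpm)
    )
}
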