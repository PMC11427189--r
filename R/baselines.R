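# Model-based comparators: 2N+1 parabolic maximization and the three-round
# Zernike-mode hill-climbing coordinate search.

#' Acquire the 2N+1 bias observations used by parabolic maximization
#'
#' For each target mode `n` the raw metric is measured with a `+b` and a
#' `-b` probe; a single unbiased metric `M0` is shared by all modes.
#'
#' @param env A [sao_env()] with a hidden aberration (see
#'   [env_set_aberration()] / [env_reset()]).
#' @param bias Observation bias `b` in um (default 0.2, the value that
#'   performs best for this method; 0.5 reproduces the shared-observation
#'   comparison arm).
#' @return Object of class `bias_observations`: list with `M0`, `Mplus`,
#'   `Mminus` (length-N vectors) and `b`.
#' @export
collect_bias_observations <- function(env, bias = 0.2) {
  stopifnot(inherits(env, "sao_env"), bias > 0)
  if (is.null(env$hidden_target)) stop("environment has no hidden aberration")
  N <- env$N
  modes <- as.character(env$target_indices)
  zero <- structure(numeric(N), names = modes)
  M0 <- .env_acquire(env, zero)
  Mp <- Mm <- numeric(N)
  for (i in seq_len(N)) {
    probe <- zero
    probe[i] <- -bias
    Mm[i] <- .env_acquire(env, probe)
    probe[i] <- bias
    Mp[i] <- .env_acquire(env, probe)
  }
  structure(list(M0 = M0, Mplus = Mp, Mminus = Mm, b = bias,
                 mode_order = env$target_indices),
            class = "bias_observations")
}

#' Per-mode correction by three-point parabolic maximization
#'
#' Fits, mode by mode, the parabola through `(-b, M-)`, `(0, M0)`,
#' `(+b, M+)` and returns the correction that moves the wavefront toward
#' the parabola vertex: `c_corr = b (M+ - M-) / (2 (2 M0 - M+ - M-))`.
#' This is the negative of the aberration estimate
#' `b (M+ - M-) / (2 M+ - 4 M0 + 2 M-)` (attached as attribute
#' `"estimate"`): on a concave metric peaked where the probe cancels a
#' hidden aberration `a`, the vertex sits at `-a` and the mirror must be
#' driven there.  Modes whose observation triple is flat or convex
#' (`2 M0 - M+ - M- <= 0`) are flagged and left uncorrected; vertex
#' magnitudes are clamped to `limit`.
#'
#' @param obs A [collect_bias_observations()] object.
#' @param limit Working clamp on the per-mode correction magnitude, um.
#' @return Named numeric correction vector with attributes `"estimate"`
#'   (the raw per-mode aberration estimate) and `"flagged"` (logical:
#'   degenerate modes).
#' @examples
#' obs <- structure(list(M0 = 1, Mplus = 0.8, Mminus = 0.6, b = 0.2,
#'                       mode_order = 4L), class = "bias_observations")
#' parabolic_correct(obs)  # +0.0333; attr "estimate" is -0.0333
#' @export
parabolic_correct <- function(obs, limit = 0.2) {
  stopifnot(inherits(obs, "bias_observations"))
  denom <- 2 * obs$M0 - obs$Mplus - obs$Mminus
  flagged <- denom <= 0
  vertex <- ifelse(flagged, 0, obs$b * (obs$Mplus - obs$Mminus) / (2 * denom))
  corr <- pmin(pmax(vertex, -limit), limit)
  names(corr) <- as.character(obs$mode_order)
  attr(corr, "estimate") <- ifelse(flagged, 0, -vertex)
  attr(corr, "flagged") <- flagged
  corr
}

#' Run parabolic maximization against an environment
#'
#' Convenience wrapper: acquires the `2N+1` bias observations and returns
#' the parabolic correction.
#'
#' @inheritParams collect_bias_observations
#' @inheritParams parabolic_correct
#' @return The [parabolic_correct()] correction vector.
#' @export
parabolic_method <- function(env, bias = 0.2, limit = 0.2) {
  parabolic_correct(collect_bias_observations(env, bias), limit)
}

#' Coordinate-search plan for Zernike-mode hill climbing
#'
#' @param limits Per-round scan half-widths in um, strictly decreasing
#'   (default `c(0.2, 0.1, 0.05)`).
#' @param n_values Odd number of uniformly spaced values scanned per mode
#'   and round (default 11; the final round then has a 0.01 um step).
#' @return Object of class `zmhc_plan`.
#' @export
zmhc_plan <- function(limits = c(0.2, 0.1, 0.05), n_values = 11) {
  stopifnot(length(limits) >= 1, all(diff(limits) < 0), all(limits > 0),
            n_values %% 2 == 1, n_values >= 3)
  structure(list(limits = limits, n_values = as.integer(n_values)),
            class = "zmhc_plan")
}

#' Zernike-mode hill climbing (coordinate search)
#'
#' For each round, each target mode in ascending Noll order is scanned with
#' `n_values` uniformly spaced correction values centred on the current
#' estimate (other modes held at their estimates); the value with the
#' highest metric is kept (first occurrence on ties).  Rounds shrink the
#' scan half-width per the plan.  With defaults and N = 12 this costs
#' 132 images per round, 396 in total, and resolves each coefficient to
#' 0.01 um.
#'
#' @param env A [sao_env()] with a hidden aberration.
#' @param plan A [zmhc_plan()].
#' @return List with `coeffs` (named correction vector, um), `image_count`
#'   (total images formed) and `best_metric`.
#' @export
zmhc_correct <- function(env, plan = zmhc_plan()) {
  stopifnot(inherits(env, "sao_env"), inherits(plan, "zmhc_plan"))
  if (is.null(env$hidden_target)) stop("environment has no hidden aberration")
  N <- env$N
  modes <- as.character(env$target_indices)
  est <- structure(numeric(N), names = modes)
  start <- env_image_count(env)
  best <- -Inf
  for (L in plan$limits) {
    offsets <- seq(-L, L, length.out = plan$n_values)
    for (i in seq_len(N)) {
      metrics <- numeric(plan$n_values)
      for (v in seq_along(offsets)) {
        cand <- est
        cand[i] <- est[i] + offsets[v]
        metrics[v] <- .env_acquire(env, cand)
      }
      est[i] <- est[i] + offsets[which.max(metrics)]
      best <- max(metrics)
    }
  }
  list(coeffs = est, image_count = env_image_count(env) - start,
       best_metric = best)
}
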