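# Single-step sensorless-AO environment. Each episode hides a random
# aberration, exposes 2N+1 sharpness observations (unbiased, then -b/+b per
# target mode), and scores a proposed correction by the ratio of the
# corrected metric to the metric with the target aberration fully removed.

#' Normalize raw sharpness metrics to [0, 1]
#'
#' Divides each metric by the maximum of the set, so the best observation
#' maps to exactly 1.
#'
#' @param m Numeric vector of nonnegative raw metric values.
#' @return `m / max(m)`.
#' @export
normalize_metrics <- function(m) {
  mx <- max(m)
  if (!is.finite(mx) || mx <= 0)
    stop("degenerate observation: all metrics are zero")
  m / mx
}

#' Observation bias code block
#'
#' The `(2N+1) x N` block of signed codes describing which mode was probed
#' in each observation: row 1 is the unbiased acquisition (all zero); then,
#' for each mode in ascending Noll order, a `-1` row followed by a `+1` row.
#'
#' @param N Number of target modes.
#' @return Integer matrix with entries in `{-1, 0, 1}`.
#' @export
observation_codes <- function(N) {
  codes <- matrix(0L, 2L * N + 1L, N)
  for (i in seq_len(N)) {
    codes[2L * i, i] <- -1L
    codes[2L * i + 1L, i] <- 1L
  }
  codes
}

#' Create a single-step sensorless-AO environment
#'
#' @param system A [system_model()].
#' @param config An [aberration_config()]; defines the hidden-aberration
#'   distribution and the target/noise mode split.
#' @param bias Observation bias amplitude in um applied to every probed
#'   mode (default 0.5).
#' @param metric_noise_sd Relative SD of optional multiplicative Gaussian
#'   metric noise (default 0, noise off).
#' @param baseline_metric Optional fixed reward denominator, emulating an
#'   in-situ benchmark metric acquired near flatness; by default the true
#'   zero-target-aberration metric (higher-order noise retained) is used,
#'   recomputed each episode.
#' @param static_offset Optional named coefficient vector (um, target
#'   modes): a fixed system aberration added to every hidden aberration,
#'   used to emulate an imperfect real instrument.
#' @param metric_fn Optional replacement for the optics pipeline: a
#'   function taking the full named coefficient vector (target modes with
#'   correction applied, then noise modes) and returning a nonnegative raw
#'   metric.  Used for analytic test oracles (e.g. exactly quadratic
#'   metrics); when supplied, `system` may be `NULL`.
#' @return Object of class `sao_env` (an R environment).
#' @examples
#' sys <- system_model(grid_size = 64, sample_image = generate_sample_image("fibers", 64, 1))
#' env <- sao_env(sys, aberration_config("B", target_indices = 4:6, noise_indices = 16:20))
#' set.seed(1)
#' obs <- env_reset(env)
#' dim(obs)  # (2*3+1) x (3+1)
#' @export
sao_env <- function(system = system_model(),
                    config = aberration_config("train_uniform"),
                    bias = 0.5, metric_noise_sd = 0,
                    baseline_metric = NULL, static_offset = NULL,
                    metric_fn = NULL) {
  stopifnot(inherits(config, "aberration_config"), bias > 0,
            metric_noise_sd >= 0)
  if (is.null(metric_fn)) stopifnot(inherits(system, "system_model"))
  e <- new.env(parent = emptyenv())
  e$system <- system
  e$metric_fn <- metric_fn
  e$config <- config
  e$target_indices <- config$target_indices
  e$noise_indices <- config$noise_indices
  e$N <- length(config$target_indices)
  e$bias <- bias
  e$metric_noise_sd <- metric_noise_sd
  e$baseline_metric <- baseline_metric
  e$static_offset <- static_offset
  e$basis <- if (is.null(metric_fn))
    make_zernike_basis(c(config$target_indices, config$noise_indices),
                       system$grid_size, system$pupil_radius)
  e$n_images <- 0L
  e$hidden_target <- NULL
  e$hidden_noise <- NULL
  e$episode_baseline <- NULL
  class(e) <- "sao_env"
  e
}

#' @export
print.sao_env <- function(x, ...) {
  cat(sprintf(paste0(
    "Sensorless-AO environment: N = %d target modes (Noll %s), bias %.2g um,\n",
    "  aberration configuration %s, %d images acquired so far\n"),
    x$N, paste(range(x$target_indices), collapse = ".."), x$bias,
    x$config$name, x$n_images))
  invisible(x)
}

# Effective hidden target including any static instrument offset.
.env_hidden <- function(env) {
  tgt <- env$hidden_target
  if (!is.null(env$static_offset))
    tgt[names(env$static_offset)] <- tgt[names(env$static_offset)] +
      env$static_offset
  tgt
}

# Acquire one image metric for a candidate correction (um, named over the
# target modes). Counts one image formation.
.env_acquire <- function(env, correction) {
  tgt <- .env_hidden(env)
  tgt[names(correction)] <- tgt[names(correction)] + correction
  m <- if (!is.null(env$metric_fn)) env$metric_fn(c(tgt, env$hidden_noise))
       else .metric_for_coeffs(env$system, env$basis, c(tgt, env$hidden_noise))
  if (env$metric_noise_sd > 0)
    m <- max(0, m * (1 + stats::rnorm(1, 0, env$metric_noise_sd)))
  env$n_images <- env$n_images + 1L
  m
}

# Reward denominator: metric with the target aberration fully removed but
# higher-order noise retained (not counted as an acquisition).
.env_baseline <- function(env) {
  if (!is.null(env$baseline_metric)) return(env$baseline_metric)
  if (is.null(env$episode_baseline)) {
    zero <- structure(numeric(env$N), names = as.character(env$target_indices))
    env$episode_baseline <- if (!is.null(env$metric_fn))
      env$metric_fn(c(zero, env$hidden_noise))
    else .metric_for_coeffs(env$system, env$basis, env$hidden_noise)
  }
  env$episode_baseline
}

#' Fix the hidden aberration of an environment
#'
#' Puts the environment into evaluation mode with a known aberration
#' instead of drawing one (used by benchmarks so that competing methods see
#' identical draws).
#'
#' @param env A [sao_env()].
#' @param target Named coefficient vector over the target modes, um.
#' @param noise Named coefficient vector over the noise modes, um
#'   (defaults to zeros).
#' @return The environment, invisibly.
#' @export
env_set_aberration <- function(env, target, noise = NULL) {
  stopifnot(inherits(env, "sao_env"))
  full <- numeric(env$N)
  names(full) <- as.character(env$target_indices)
  full[names(target)] <- target
  env$hidden_target <- full
  nz <- numeric(length(env$noise_indices))
  names(nz) <- as.character(env$noise_indices)
  if (!is.null(noise)) nz[names(noise)] <- noise
  env$hidden_noise <- nz
  env$episode_baseline <- NULL
  invisible(env)
}

#' Start an episode and build the observation matrix
#'
#' Draws a fresh hidden aberration (target modes plus higher-order noise)
#' unless one is supplied, then acquires `2N+1` sharpness metrics: the
#' unbiased wavefront first, then `-bias` and `+bias` probes of each target
#' mode in ascending Noll order.  Metrics are normalized by their maximum.
#'
#' @param env A [sao_env()].
#' @param aberration Optional list with `target` and `noise` named
#'   coefficient vectors (um) to use instead of a random draw.
#' @return The `(2N+1) x (N+1)` observation matrix: normalized metric
#'   column followed by the `{-1, 0, 1}` code block.
#' @export
env_reset <- function(env, aberration = NULL) {
  stopifnot(inherits(env, "sao_env"))
  if (is.null(aberration)) aberration <- sample_aberration(env$config)
  env_set_aberration(env, aberration$target, aberration$noise)
  N <- env$N
  modes <- as.character(env$target_indices)
  m <- numeric(2L * N + 1L)
  zero <- structure(numeric(N), names = modes)
  m[1L] <- .env_acquire(env, zero)
  for (i in seq_len(N)) {
    probe <- zero
    probe[i] <- -env$bias
    m[2L * i] <- .env_acquire(env, probe)
    probe[i] <- env$bias
    m[2L * i + 1L] <- .env_acquire(env, probe)
  }
  obs <- cbind(normalize_metrics(m), observation_codes(N))
  colnames(obs) <- c("metric", modes)
  obs
}

#' Score a correction and terminate the episode
#'
#' Applies the action as a correction added to the hidden target aberration
#' (higher-order noise stays) and returns the reward: the corrected metric
#' divided by the metric of the zero-target-aberration wavefront (or a
#' fixed `baseline_metric`).  Episodes are single-step, so `done` is always
#' `TRUE`.
#'
#' @param env A [sao_env()] with a hidden aberration (after [env_reset()]).
#' @param action Numeric vector of N correction coefficients, um.
#' @return List with `reward` and `done = TRUE`.
#' @export
env_step <- function(env, action) {
  stopifnot(inherits(env, "sao_env"))
  if (is.null(env$hidden_target)) stop("call env_reset() first")
  if (length(action) != env$N || any(!is.finite(action)))
    stop("action must be ", env$N, " finite coefficients")
  names(action) <- as.character(env$target_indices)
  list(reward = .env_acquire(env, action) / .env_baseline(env), done = TRUE)
}

#' Evaluate a base action under several exploration-noise profiles
#'
#' Single-step episodes admit many action evaluations against the same
#' hidden aberration: each noise profile is added to the base action and
#' scored by [env_step()] semantics, costing one image formation each.
#'
#' @param env A [sao_env()] with a hidden aberration.
#' @param base_action Numeric vector of N coefficients, um.
#' @param noise_profiles `k x N` matrix of action perturbations, um.
#' @return Numeric vector of `k` rewards.
#' @export
evaluate_action_batch <- function(env, base_action, noise_profiles) {
  stopifnot(inherits(env, "sao_env"))
  noise_profiles <- as.matrix(noise_profiles)
  if (ncol(noise_profiles) != env$N) stop("noise profiles must have N columns")
  vapply(seq_len(nrow(noise_profiles)), function(i)
    env_step(env, base_action + noise_profiles[i, ])$reward, numeric(1))
}

#' Number of images acquired by an environment so far
#'
#' @param env A [sao_env()].
#' @param reset Reset the counter to zero after reading.
#' @return Integer count of image formations.
#' @export
env_image_count <- function(env, reset = FALSE) {
  n <- env$n_images
  if (reset) env$n_images <- 0L
  n
}
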