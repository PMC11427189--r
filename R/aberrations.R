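# Random aberration generation: target-mode distributions (configurations
# A, B, C) plus small higher-order-mode noise emulating residual,
# uncorrectable wavefront content.

# Zero-mean Gaussian constrained to [-clip, clip] by resampling offenders,
# i.e. an exact truncated normal (no probability atoms at the limits).
.rnorm_trunc <- function(n, sd, clip) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > clip)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > clip]
  }
  x
}

#' Aberration distribution configuration
#'
#' Defines per-mode distributions of the target Zernike coefficients
#' (Noll 4..15) and the higher-order noise modes (Noll 16..28), in um:
#'
#' * `"A"` / `"train_uniform"`: iid uniform on `[-0.15, 0.15]` (the
#'   distribution seen during training).
#' * `"B"`: iid zero-mean Gaussian, SD 0.06 (0.4 x the 0.15 limit),
#'   constrained to `[-0.15, 0.15]`.
#' * `"C"`: Gaussian with SD decreasing by radial-order group — 0.08 um for
#'   modes 4..6, 0.06 um for 7..10, 0.04 um for 11..15 — constrained to
#'   `[-0.2, 0.2]` (exercises extrapolation beyond the training limit).
#'
#' Higher-order noise is always Gaussian SD 0.01 um constrained to
#' `[-0.025, 0.025]`.  Constraints are enforced by resampling until inside
#' (a true truncated normal), not by clamping to the boundary.
#'
#' @param name Configuration name.
#' @param target_indices Noll indices of the corrected modes.
#' @param noise_indices Noll indices of the uncorrected noise modes.
#' @param noise_sd,noise_clip Higher-order noise SD and limit, um.
#' @return Object of class `aberration_config` with per-mode `dist`
#'   (`"uniform"`/`"gaussian"`), `sd` and `limit` vectors over
#'   `target_indices`.
#' @examples
#' aberration_config("C")$sd
#' @export
aberration_config <- function(name = c("A", "B", "C", "train_uniform"),
                              target_indices = 4:15,
                              noise_indices = 16:28,
                              noise_sd = 0.01, noise_clip = 0.025) {
  name <- match.arg(name)
  if (length(intersect(target_indices, noise_indices)))
    stop("target and noise indices must be disjoint")
  k <- length(target_indices)
  cfg <- switch(name,
    A = ,
    train_uniform = list(dist = rep("uniform", k), sd = rep(NA_real_, k),
                         limit = rep(0.15, k)),
    B = list(dist = rep("gaussian", k), sd = rep(0.06, k),
             limit = rep(0.15, k)),
    C = {
      sd <- ifelse(target_indices <= 6, 0.08,
                   ifelse(target_indices <= 10, 0.06, 0.04))
      list(dist = rep("gaussian", k), sd = sd, limit = rep(0.2, k))
    })
  structure(
    list(name = name, target_indices = as.integer(target_indices),
         noise_indices = as.integer(noise_indices),
         dist = cfg$dist, sd = cfg$sd, limit = cfg$limit,
         noise_sd = noise_sd, noise_clip = noise_clip),
    class = "aberration_config")
}

#' @export
print.aberration_config <- function(x, ...) {
  cat(sprintf("Aberration configuration %s: %d target modes (Noll %s), %d noise modes\n",
              x$name, length(x$target_indices),
              paste(range(x$target_indices), collapse = ".."),
              length(x$noise_indices)))
  invisible(x)
}

#' Draw target-mode Zernike coefficients
#'
#' @param config An [aberration_config()] object.
#' @return Named numeric vector (um), one entry per target mode, each
#'   within the configuration limit.  Uses the R session RNG; seed with
#'   [set.seed()].
#' @export
sample_target_aberration <- function(config) {
  stopifnot(inherits(config, "aberration_config"))
  k <- length(config$target_indices)
  out <- numeric(k)
  uni <- config$dist == "uniform"
  if (any(uni))
    out[uni] <- stats::runif(sum(uni), -config$limit[uni], config$limit[uni])
  for (i in which(!uni))
    out[i] <- .rnorm_trunc(1, config$sd[i], config$limit[i])
  names(out) <- as.character(config$target_indices)
  out
}

#' Draw higher-order-mode noise coefficients
#'
#' @param config An [aberration_config()] object.
#' @return Named numeric vector (um) over the configured noise modes,
#'   Gaussian with the configured SD, constrained to the noise limit.
#' @export
sample_higher_order_noise <- function(config) {
  stopifnot(inherits(config, "aberration_config"))
  out <- .rnorm_trunc(length(config$noise_indices), config$noise_sd,
                      config$noise_clip)
  names(out) <- as.character(config$noise_indices)
  out
}

#' Draw a complete aberration sample (target modes plus noise)
#'
#' @param config An [aberration_config()] object.
#' @return List with `target` and `noise` named coefficient vectors, um.
#' @export
sample_aberration <- function(config) {
  list(target = sample_target_aberration(config),
       noise = sample_higher_order_noise(config))
}
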