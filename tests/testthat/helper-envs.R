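# Shared fixtures, all built in code.

# Small, fast optical system for tests that exercise the full pipeline.
tiny_system <- function(size = 64, ...) {
  system_model(grid_size = size, pupil_radius = size %/% 2 - 1,
               sample_image = generate_sample_image("fibers", size, seed = 99L),
               ...)
}

# Environment with an exactly quadratic, separable metric
# m = level - kappa * sum((a_i + c_i)^2) over the target modes: the analytic
# oracle on which parabolic maximization and ZMHC are exact.
quadratic_env <- function(target_indices = 4:15, kappa = 0.4, level = 1,
                          bias = 0.5, noise_indices = 16:18) {
  cfg <- aberration_config("B", target_indices = target_indices,
                           noise_indices = noise_indices)
  tgt_names <- as.character(target_indices)
  sao_env(system = NULL, config = cfg, bias = bias,
          metric_fn = function(coeffs) {
            max(0, level - kappa * sum(coeffs[tgt_names]^2))
          })
}

# Independent recomputation of the Noll radial polynomial via the explicit
# factorial series at a single point (scalar, no vectorization reuse).
oracle_zernike_point <- function(j, x, y) {
  n <- 0
  while (j > (n + 1) * (n + 2) / 2) n <- n + 1
  p <- j - n * (n + 1) / 2
  m <- if (n %% 2 == 0) 2 * floor(p / 2) else 2 * floor((p + 1) / 2) - 1
  r <- sqrt(x^2 + y^2)
  if (r > 1) return(0)
  th <- atan2(y, x)
  rad <- 0
  for (k in 0:((n - m) / 2))
    rad <- rad + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      r^(n - 2 * k)
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m == 0) 1 else if (j %% 2 == 1) sin(m * th) else cos(m * th)
  norm * rad * ang
}
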