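#' Read a run configuration from YAML
#'
#' Builds the optical system, environment and training schedule from a
#' YAML file with (all optional) top-level keys `optics:`, `env:` and
#' `training:`.  `optics:` accepts the [system_model()] arguments plus a
#' `sample:` sub-key (`kind`, `size`, `seed`, or `path` to a TIFF/PNG);
#' `env:` accepts `aberration_config`, `bias`, `metric_noise_sd`;
#' `training:` accepts the [training_schedule()] arguments.
#'
#' @param path Path to the YAML file.
#' @return List with `system`, `env` and `schedule`.
#' @export
read_sao_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  opt <- cfg$optics %||% list()
  sample <- NULL
  if (!is.null(opt$sample)) {
    s <- opt$sample
    sample <- if (!is.null(s$path)) read_sample_image(s$path)
    else generate_sample_image(s$kind %||% "fibers", s$size %||% 128,
                               seed = s$seed)
    opt$sample <- NULL
  }
  system <- do.call(system_model, c(opt, list(sample_image = sample)))

  envc <- cfg$env %||% list()
  config <- aberration_config(envc$aberration_config %||% "train_uniform",
                              target_indices = envc$target_indices %||% 4:15,
                              noise_indices = envc$noise_indices %||% 16:28)
  env <- sao_env(system, config,
                 bias = envc$bias %||% 0.5,
                 metric_noise_sd = envc$metric_noise_sd %||% 0)

  schedule <- do.call(training_schedule, cfg$training %||% list())
  list(system = system, env = env, schedule = schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
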