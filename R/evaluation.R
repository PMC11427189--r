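# Residual-error metrics and the Monte Carlo benchmark harness.

#' Residual RMS wavefront error over the corrected modes
#'
#' With orthonormal Zernike modes the RMS wavefront error of the residual
#' equals the Euclidean norm of the residual coefficient vector:
#' `sqrt(sum_i (c_i + c_i^corr)^2)` over the target modes.  Higher-order
#' noise modes are deliberately excluded: the score isolates the accuracy
#' on the modes a method can actually correct, so the conventional
#' full-wavefront RMS would be somewhat higher.
#'
#' @param true_coeffs Named or plain numeric vector: the hidden target
#'   aberration, um.
#' @param predicted_correction Numeric vector of the same length: the
#'   applied correction, um.
#' @return RMS wavefront error in um (0 iff exact cancellation).
#' @examples
#' rms_wfe(c(0.003, 0.004), c(0, 0)) # 0.005
#' @export
rms_wfe <- function(true_coeffs, predicted_correction) {
  if (length(true_coeffs) != length(predicted_correction))
    stop("coefficient vectors must have equal length")
  if (!is.null(names(true_coeffs)) && !is.null(names(predicted_correction)))
    predicted_correction <- predicted_correction[names(true_coeffs)]
  sqrt(sum((true_coeffs + predicted_correction)^2))
}

#' Marechal criterion for diffraction-limited RMS wavefront error
#'
#' @param wavelength Wavelength in um.
#' @return `wavelength / 14`, um: residuals below this RMS are
#'   conventionally considered diffraction-limited.
#' @examples
#' marechal_threshold(0.488) # 0.0349 um
#' @export
marechal_threshold <- function(wavelength) {
  stopifnot(wavelength > 0)
  wavelength / 14
}

#' Monte Carlo benchmark of a correction method
#'
#' Draws `n_trials` aberrations from a configuration, runs the chosen
#' method on each, and scores the residual RMS wavefront error over the
#' target modes.  All aberrations are drawn up front from the supplied
#' seed, so two methods benchmarked with the same seed and configuration
#' experience bitwise-identical aberration sequences.
#'
#' @param method One of `"zero"` (no correction), `"parabolic"`,
#'   `"zmhc"`, `"agent"`.
#' @param config An [aberration_config()] or a configuration name.
#' @param n_trials Number of trials.
#' @param system A [system_model()] (ignored when `metric_fn` is given).
#' @param bias Observation bias for `"parabolic"`, um.
#' @param agent A trained [moss_ddpg()] agent (for `method = "agent"`;
#'   its own observation bias is used).
#' @param plan A [zmhc_plan()] (for `method = "zmhc"`).
#' @param limit Correction clamp for `"parabolic"`, um.
#' @param seed Integer seed for the aberration draws.
#' @param metric_fn Optional metric override passed to [sao_env()].
#' @return Object of class `sao_benchmark`: per-trial results plus mean,
#'   SD and the fraction of trials below the Marechal threshold (both the
#'   empirical count and the Gaussian approximation
#'   `Phi((threshold - mean)/sd)`).
#' @export
run_benchmark <- function(method = c("zero", "parabolic", "zmhc", "agent"),
                          config = aberration_config("B"), n_trials = 1000,
                          system = system_model(), bias = 0.2, agent = NULL,
                          plan = zmhc_plan(), limit = 0.2, seed = 1,
                          metric_fn = NULL) {
  method <- match.arg(method)
  if (is.character(config)) config <- aberration_config(config)
  if (method == "agent" && !inherits(agent, "moss_ddpg"))
    stop("method 'agent' requires a trained moss_ddpg agent")

  set.seed(seed)
  draws <- replicate(n_trials, sample_aberration(config), simplify = FALSE)

  env_bias <- if (method == "agent") agent$bias else bias
  env <- sao_env(system = system, config = config, bias = env_bias,
                 metric_fn = metric_fn)
  if (method == "agent" && agent$N != env$N)
    stop("agent trained for N = ", agent$N, " modes, environment has ", env$N)

  wavelength <- if (is.null(metric_fn)) env$system$wavelength else 0.488
  thr <- marechal_threshold(wavelength)

  rms <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    ab <- draws[[i]]
    corr <- switch(method,
      zero = numeric(env$N),
      parabolic = {
        env_set_aberration(env, ab$target, ab$noise)
        parabolic_method(env, bias = bias, limit = limit)
      },
      zmhc = {
        env_set_aberration(env, ab$target, ab$noise)
        zmhc_correct(env, plan)$coeffs
      },
      agent = {
        obs <- env_reset(env, aberration = ab)
        predict(agent, obs)
      })
    rms[i] <- rms_wfe(ab$target, corr)
  }

  structure(list(
    method = method, config = config$name, n_trials = n_trials, seed = seed,
    bias = if (method %in% c("parabolic", "agent")) env_bias else NA_real_,
    trials = data.frame(trial = seq_len(n_trials), config = config$name,
                        method = method, rms_wfe = rms),
    mean_rms = mean(rms), sd_rms = stats::sd(rms),
    threshold = thr,
    frac_below_empirical = mean(rms < thr),
    frac_below_gaussian = stats::pnorm((thr - mean(rms)) / stats::sd(rms)),
    images = env_image_count(env)),
    class = "sao_benchmark")
}

#' @export
print.sao_benchmark <- function(x, ...) {
  cat(sprintf(paste0(
    "SAO correction benchmark: method '%s', configuration %s, %d trials\n",
    "  mean RMS-WFE : %.4f um (SD %.4f)\n",
    "  below Marechal threshold (%.4f um): %.1f%% empirical, %.1f%% Gaussian\n"),
    x$method, x$config, x$n_trials, x$mean_rms, x$sd_rms, x$threshold,
    100 * x$frac_below_empirical, 100 * x$frac_below_gaussian))
  invisible(x)
}

#' @export
as.data.frame.sao_benchmark <- function(x, ...) x$trials
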