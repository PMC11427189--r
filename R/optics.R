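# Fourier-optics model of the confocal SLO branch: generalized pupil ->
# intensity PSF -> double-pass effective PSF with a multimode-fiber detector
# -> image formation by convolution -> sharpness metric.

fftshift <- function(x) {
  d <- dim(x)
  i <- c(seq((d[1] %/% 2) + 1, d[1]), seq_len(d[1] %/% 2))
  j <- c(seq((d[2] %/% 2) + 1, d[2]), seq_len(d[2] %/% 2))
  x[i, j, drop = FALSE]
}

ifftshift <- function(x) {
  d <- dim(x)
  i <- c(seq(d[1] - (d[1] %/% 2) + 1, d[1]), seq_len(d[1] - (d[1] %/% 2)))
  j <- c(seq(d[2] - (d[2] %/% 2) + 1, d[2]), seq_len(d[2] - (d[2] %/% 2)))
  x[i, j, drop = FALSE]
}

# Wrapped index window of half-width hw around origin pixel 1: offsets
# 0..hw then -hw..-1.
.wrap_window <- function(n, hw) c(seq_len(hw + 1L), seq(n - hw + 1L, n))

#' Describe the simulated confocal SLO optical system
#'
#' Collects the optical parameters and precomputes everything that is fixed
#' per system: the pupil mask, the detection-fiber kernel spectrum, and the
#' sample-image spectrum.  The pupil grid is zero-padded by `pad_factor`
#' before the FFT so the diffraction-limited core spans several PSF pixels.
#'
#' @param wavelength Laser wavelength in um (default 0.488).
#' @param dm_gain Dimensionless coefficient-to-wavefront gain: one
#'   commanded micrometre of a deformable-mirror Zernike mode produces
#'   `dm_gain` um of optical path difference at the pupil.  Real DM paths
#'   have gains well below 1 (pupil demagnification, actuator influence
#'   functions, reflection geometry); the default 0.28 is the package's
#'   calibration of this unprinted instrument constant, chosen so the
#'   simulated metric-coefficient response and the model-based correction
#'   accuracy match the scale reported for the physical instrument.
#' @param grid_size Pupil grid side length in pixels (default 128).
#' @param pupil_radius Pupil radius in pixels (default `grid_size/2 - 1`).
#' @param fiber_diameter Detection fiber diameter in Airy-disk-diameter
#'   units; 0 models an ideal point detector (confocal pinhole limit).
#' @param sample_image Nonnegative numeric matrix: the fluorescence
#'   reflectance/emission profile of the sample.  Defaults to a reproducible
#'   synthetic lens-tissue fibre texture of side 128.
#' @param pad_factor Zero-padding factor for the PSF FFT (default 2).
#' @param kernel_size Odd side length of the effective-PSF kernel used for
#'   image formation (default 33); the effective PSF is cropped to this
#'   central window before convolution with the sample.
#' @param background Constant detected background added to every image
#'   pixel at acquisition time, expressed as a multiple of the mean pixel
#'   intensity of the diffraction-limited image (default 0: ideal
#'   background-free detection).  A positive value emulates the
#'   aberration-independent signal floor of a real detector channel
#'   (out-of-focus fluorescence, stray light, electronic offset), which
#'   compresses the relative response of the sharpness metric.
#' @return Object of class `system_model`.
#' @examples
#' sys <- system_model(grid_size = 64, sample_image = matrix(1, 64, 64))
#' sys
#' @export
system_model <- function(wavelength = 0.488, dm_gain = 0.28, grid_size = 128,
                         pupil_radius = grid_size %/% 2 - 1,
                         fiber_diameter = 4, sample_image = NULL,
                         pad_factor = 2, kernel_size = 33, background = 0) {
  stopifnot(wavelength > 0, dm_gain > 0, fiber_diameter >= 0, pad_factor >= 1,
            background >= 0)
  if (is.null(sample_image))
    sample_image <- generate_sample_image("fibers", 128, seed = 20240723L)
  sample_image <- as.matrix(sample_image)
  if (any(!is.finite(sample_image)) || any(sample_image < 0))
    stop("sample_image must be finite and nonnegative")
  if (max(sample_image) <= 0)
    stop("sample_image must have at least one positive pixel")
  if (nrow(sample_image) != ncol(sample_image))
    stop("sample_image must be square")
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")

  grid_size <- as.integer(grid_size)
  P <- as.integer(pad_factor * grid_size)
  centre <- grid_size %/% 2L + 1L
  x <- (seq_len(grid_size) - centre) / (pupil_radius + 0.5)
  X <- matrix(x, grid_size, grid_size)
  mask <- sqrt(X^2 + t(X)^2) <= 1

  # Airy disk diameter on the padded FFT grid, in pixels.
  pupil_diam_px <- 2L * as.integer(pupil_radius) + 1L
  add_px <- 2 * 1.22 * P / pupil_diam_px

  # Uniform unit-height disk as the fiber's intensity response, stored
  # origin-centred (unshifted) together with its spectrum.
  fiber_fft <- NULL
  if (fiber_diameter > 0) {
    cs <- P %/% 2L + 1L
    fx <- matrix(seq_len(P) - cs, P, P)
    fiber <- (sqrt(fx^2 + t(fx)^2) <= fiber_diameter * add_px / 2) * 1
    fiber_fft <- stats::fft(ifftshift(fiber))
  }

  S <- nrow(sample_image)
  ks <- min(kernel_size, if (S %% 2 == 1) S else S - 1L)
  sample_fft <- stats::fft(sample_image)

  sys <- structure(
    list(wavelength = wavelength, dm_gain = dm_gain, grid_size = grid_size,
         pupil_radius = pupil_radius, fiber_diameter = fiber_diameter,
         sample_image = sample_image, pad_factor = pad_factor,
         kernel_size = as.integer(ks), background = background,
         fft_size = P, pupil_mask = mask, airy_diameter_px = add_px,
         fiber_fft = fiber_fft, sample_fft = sample_fft,
         sample_power = Mod(sample_fft)^2, sample_size = S,
         sample_sum = sum(sample_image), background_level = 0),
    class = "system_model")
  if (background > 0) {
    # absolute floor: `background` x mean pixel of the aberration-free image
    hs0 <- .effective_unshifted(sys, .psf_unshifted(sys, 0 * mask))
    hw <- (sys$kernel_size - 1L) %/% 2L
    wP <- .wrap_window(P, hw)
    ksum <- sum(hs0[wP, wP])
    sys$background_level <- background * ksum * sum(sample_image) / S^2
  }
  sys
}

#' Absolute detected-background level of a system
#'
#' @param system A [system_model()] object.
#' @return The constant intensity added to every detected pixel.
#' @export
detector_background <- function(system) system$background_level

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Confocal SLO system model\n",
    "  wavelength    : %.3f um (DM gain %.2g)\n",
    "  pupil grid    : %dx%d px (radius %d px), FFT grid %dx%d\n",
    "  fiber diameter: %s\n",
    "  sample image  : %dx%d px\n",
    "  background    : %.2g x diffraction-limited mean intensity\n"),
    x$wavelength, x$dm_gain, x$grid_size, x$grid_size, x$pupil_radius,
    x$fft_size, x$fft_size,
    if (x$fiber_diameter == 0) "point detector"
    else sprintf("%.2g Airy disk diameters (%.1f px)",
                 x$fiber_diameter, x$fiber_diameter * x$airy_diameter_px),
    x$sample_size, x$sample_size, x$background))
  invisible(x)
}

#' Replace the sample image of a system model
#'
#' @param system A [system_model()] object.
#' @param sample_image Nonnegative square numeric matrix.
#' @return The updated `system_model`.
#' @export
set_sample_image <- function(system, sample_image) {
  stopifnot(inherits(system, "system_model"))
  system_model(wavelength = system$wavelength, dm_gain = system$dm_gain,
               grid_size = system$grid_size,
               pupil_radius = system$pupil_radius,
               fiber_diameter = system$fiber_diameter,
               sample_image = sample_image, pad_factor = system$pad_factor,
               kernel_size = system$kernel_size,
               background = system$background)
}

# Unshifted intensity PSF (DC at [1,1]) from an OPD map in um.
.psf_unshifted <- function(system, opd) {
  phase <- system$dm_gain * (2 * pi / system$wavelength) * opd
  field <- matrix(0i, system$fft_size, system$fft_size)
  g <- system$grid_size
  field[seq_len(g), seq_len(g)] <-
    system$pupil_mask * exp(-1i * phase)
  Mod(stats::fft(field))^2
}

# Unshifted effective PSF from an unshifted single-pass PSF (h1 = h2 = h:
# identical aberration on the illumination and detection passes).
.effective_unshifted <- function(system, h) {
  if (system$fiber_diameter == 0) return(h * h)
  conv <- Re(stats::fft(stats::fft(h) * system$fiber_fft, inverse = TRUE)) /
    system$fft_size^2
  h * pmax(conv, 0)
}

# Sharpness metric for a coefficient map without materializing the image:
# crops the effective PSF to the central kernel, embeds it on the sample
# grid and applies Parseval to the circular convolution.
.metric_unshifted <- function(system, hs) {
  hw <- (system$kernel_size - 1L) %/% 2L
  wP <- .wrap_window(system$fft_size, hw)
  wS <- .wrap_window(system$sample_size, hw)
  kern <- matrix(0, system$sample_size, system$sample_size)
  kern[wS, wS] <- hs[wP, wP]
  m <- sum(Mod(stats::fft(kern))^2 * system$sample_power) / system$sample_size^2
  B <- system$background_level
  if (B > 0)  # Parseval form of sum((I + B)^2) over the detected image
    m <- m + 2 * B * sum(kern) * system$sample_sum + system$sample_size^2 * B^2
  m
}

# Full pipeline: named coefficient vector (um) -> sharpness metric.
.metric_for_coeffs <- function(system, basis, coeffs) {
  full <- numeric(length(basis$noll_indices))
  names(full) <- as.character(basis$noll_indices)
  if (length(coeffs)) full[names(coeffs)] <- coeffs
  opd <- matrix(basis$basis_matrix %*% full, basis$grid_size, basis$grid_size)
  .metric_unshifted(system, .effective_unshifted(system, .psf_unshifted(system, opd)))
}

#' Compute the intensity point spread function of an aberrated pupil
#'
#' The generalized pupil is `P = A exp(-j (2*pi/lambda) W)` with `A` the
#' binary pupil transmission and `W` the optical path difference in um; the
#' intensity PSF is the squared magnitude of its (zero-padded) Fourier
#' transform, returned fftshift-centred.
#'
#' @param wavefront A [compose_wavefront()] object, or a bare numeric matrix
#'   of OPD values in um on the pupil grid.
#' @param system A [system_model()] object.
#' @param kind PSF label, one of `"illumination"`, `"detection"`,
#'   `"effective"`.
#' @return Object of class `psf`: list with `intensity` (nonnegative matrix,
#'   centre at `fft_size/2 + 1`) and `kind`.
#' @export
compute_psf <- function(wavefront, system, kind = "illumination") {
  stopifnot(inherits(system, "system_model"))
  opd <- if (inherits(wavefront, "wavefront")) wavefront$opd else wavefront
  if (!is.matrix(opd) || nrow(opd) != system$grid_size ||
      ncol(opd) != system$grid_size)
    stop("wavefront OPD must be a grid_size x grid_size matrix")
  structure(list(intensity = fftshift(.psf_unshifted(system, opd)),
                 kind = match.arg(kind, c("illumination", "detection", "effective"))),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("%s PSF, %dx%d px, total energy %.4g\n",
              x$kind, nrow(x$intensity), ncol(x$intensity), sum(x$intensity)))
  invisible(x)
}

#' Effective confocal PSF from illumination and detection PSFs
#'
#' With a point detector the effective PSF is the pointwise product
#' `hs = h1 * h2`.  A multimode collection fiber of finite diameter is
#' modelled as a uniform unit-height disk `f`; the effective PSF is then
#' `hs = h1 * (f (*) h2)` with `(*)` circular convolution.
#'
#' @param h1,h2 Illumination and detection [compute_psf()] objects (or bare
#'   matrices of equal size, fftshift-centred).
#' @param system A [system_model()] object (supplies the fiber diameter).
#' @return Object of class `psf`, kind `"effective"`.
#' @export
effective_psf <- function(h1, h2, system) {
  stopifnot(inherits(system, "system_model"))
  m1 <- if (inherits(h1, "psf")) h1$intensity else h1
  m2 <- if (inherits(h2, "psf")) h2$intensity else h2
  if (!identical(dim(m1), dim(m2))) stop("h1 and h2 must have the same shape")
  if (system$fiber_diameter == 0) {
    hs <- m1 * m2
  } else {
    if (!identical(dim(m1), dim(system$fiber_fft)))
      stop("PSF shape does not match the system FFT grid")
    conv <- Re(stats::fft(stats::fft(ifftshift(m2)) * system$fiber_fft,
                          inverse = TRUE)) / length(m2)
    hs <- m1 * fftshift(pmax(conv, 0))
  }
  structure(list(intensity = hs, kind = "effective"), class = "psf")
}

#' Form a confocal image by convolving the effective PSF with the sample
#'
#' The effective PSF is cropped to the system's central kernel window and
#' circularly convolved (FFT-based) with the sample fluorescence profile.
#'
#' @param hs Effective [compute_psf()]/[effective_psf()] object or bare
#'   fftshift-centred matrix.
#' @param sample_image Nonnegative square matrix; defaults to the system's.
#' @param system A [system_model()] object.
#' @return Nonnegative image matrix, same size as `sample_image`.
#' @export
render_image <- function(hs, sample_image = NULL, system) {
  stopifnot(inherits(system, "system_model"))
  m <- if (inherits(hs, "psf")) hs$intensity else hs
  if (is.null(sample_image)) sample_image <- system$sample_image
  S <- nrow(sample_image)
  hw <- (min(system$kernel_size, if (S %% 2 == 1) S else S - 1L) - 1L) %/% 2L
  mu <- ifftshift(m)
  wP <- .wrap_window(nrow(m), hw)
  wS <- .wrap_window(S, hw)
  kern <- matrix(0, S, S)
  kern[wS, wS] <- mu[wP, wP]
  img <- Re(stats::fft(stats::fft(kern) * stats::fft(sample_image),
                       inverse = TRUE)) / S^2
  pmax(img, 0)
}

#' Image sharpness metric: sum of squared pixel intensities
#'
#' @param image Nonnegative numeric matrix (or vector).
#' @return Scalar metric `m = sum_p I_p^2 >= 0`.
#' @examples
#' sharpness_metric(matrix(c(1, 2), 1, 2)) # 5
#' @export
sharpness_metric <- function(image) {
  if (any(image < 0)) stop("image must be nonnegative")
  sum(image^2)
}
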