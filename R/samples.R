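# Synthetic confocal sample textures. These emulate the two sample classes
# used on the bench — lens-tissue fibres (wide and thin strokes) and
# ganglion-cell mosaics — well enough to exercise the sharpness metric;
# they carry no biological content.

# Gaussian blur by circular convolution with a wrapped isotropic kernel.
.blur <- function(img, sigma) {
  n <- nrow(img)
  d <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  g1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(k) * stats::fft(img), inverse = TRUE)) / n^2
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.texture_fibers <- function(size) {
  wide <- matrix(0, size, size)
  thin <- matrix(0, size, size)
  n_curves <- max(6L, round(size / 12))
  for (cv in seq_len(n_curves)) {
    len <- round(stats::runif(1, 0.8, 1.6) * size)
    pos <- stats::runif(2, 1, size)
    ang <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(0, len, 2)
    for (s in seq_len(len)) {
      ang <- ang + stats::rnorm(1, 0, 0.09)
      pos <- pos + c(cos(ang), sin(ang))
      pts[s, ] <- ((pos - 1) %% size) + 1
    }
    ij <- cbind(round(pts[, 1]), round(pts[, 2]))
    ij <- ((ij - 1L) %% size) + 1L
    if (cv %% 2 == 0) wide[ij] <- 1 else thin[ij] <- 1
  }
  img <- .blur(wide, 1.6) / 0.05 + 0.85 * .blur(thin, 0.75) / 0.05
  img <- img / max(img)
  pmax(img, 0)
}

.texture_cells <- function(size) {
  spacing <- size / 16
  img <- matrix(0, size, size)
  ys <- seq(1, size, by = spacing * sqrt(3) / 2)
  for (r in seq_along(ys)) {
    xs <- seq(1 + (r %% 2) * spacing / 2, size, by = spacing)
    for (x in xs) {
      cx <- ((round(x + stats::rnorm(1, 0, spacing * 0.15)) - 1) %% size) + 1
      cy <- ((round(ys[r] + stats::rnorm(1, 0, spacing * 0.15)) - 1) %% size) + 1
      img[cx, cy] <- stats::runif(1, 0.5, 1)
    }
  }
  img <- .blur(img, spacing * 0.2)
  img / max(img)
}

#' Generate a reproducible synthetic sample texture
#'
#' @param kind One of `"fibers"` (sparse smooth curves with wide and thin
#'   stroke widths), `"cells"` (jittered hexagonal mosaic of soft disks) or
#'   `"mixed"` (a field of view containing both, in diagonal quadrants).
#' @param size Image side length in pixels (>= 64).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return Nonnegative numeric matrix normalized to `[0, 1]`.
#' @examples
#' img <- generate_sample_image("fibers", 64, seed = 1)
#' range(img)
#' @export
generate_sample_image <- function(kind = c("fibers", "cells", "mixed"),
                                  size = 128, seed = NULL) {
  kind <- match.arg(kind)
  if (size < 64) stop("size must be >= 64")
  .with_seed(seed, switch(kind,
    fibers = .texture_fibers(size),
    cells  = .texture_cells(size),
    mixed  = {
      # field of view containing both tissue types, in diagonal quadrants
      f <- .texture_fibers(size)
      cl <- .texture_cells(size)
      h <- size %/% 2
      f[1:h, (h + 1):size] <- cl[1:h, (h + 1):size]
      f[(h + 1):size, 1:h] <- cl[(h + 1):size, 1:h]
      f
    }))
}

#' Read a grayscale sample image from TIFF or PNG
#'
#' Multi-channel images are averaged to one channel; values are shifted to
#' be nonnegative if needed.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Nonnegative numeric matrix.
#' @export
read_sample_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' is required to read PNG images")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img <- img - min(0, min(img))
  img
}
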