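# Seeded synthetic cyst phantoms: smooth textured background with disk
# targets, corrupted by additive Gaussian noise or unit-mean multiplicative
# speckle. Everything needed to exercise the enhancement pipeline without
# any real acquisition.

#' Specify a synthetic ultrasound-like phantom
#'
#' Describes a toy B-mode scene: a uniform background with a smooth
#' low-frequency texture, disk-shaped targets (dark disks mimic anechoic
#' cysts, bright ones dense echo spots), and a noise model. The default
#' scene is a 128 x 128 image with two anechoic cysts and one bright spot
#' on a mid-gray background, degraded by additive Gaussian noise of
#' standard deviation 0.1 — the regime in which universal-threshold
#' shrinkage is motivated.
#'
#' @param shape image dimensions \code{c(rows, cols)}.
#' @param backgroundLevel background intensity in [0, 1].
#' @param cysts list of targets, each \code{list(center = c(row, col),
#'   radius = pixels, intensity = value in [0, 1])}. Every disk must lie
#'   fully inside the image. \code{NULL} (default) lays out two anechoic
#'   cysts and one bright echo spot scaled to the image size.
#' @param textureAmplitude peak amplitude of the smooth background texture
#'   (0 disables it).
#' @param noiseModel \code{"gaussian_additive"} (default) or
#'   \code{"speckle_multiplicative"} (unit-mean Rayleigh-derived field,
#'   scaled so its standard deviation is \code{noiseSigma}).
#' @param noiseSigma noise standard deviation (0 disables noise).
#' @param seed integer seed; the same spec always yields the same images.
#' @return a list of class \code{"PhantomSpec"}.
#' @seealso [makePhantom()], [phantomMasks()]
#' @export
phantomSpec <- function(shape = c(128, 128),
                        backgroundLevel = 0.55,
                        cysts = NULL,
                        textureAmplitude = 0.05,
                        noiseModel = c("gaussian_additive", "speckle_multiplicative"),
                        noiseSigma = 0.1,
                        seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L))
    stop("'shape' must be c(rows, cols) with both >= 4")
  if (is.null(cysts)) {
    # default scene, laid out relative to the image size: two anechoic
    # cysts plus one small bright echo spot
    r <- shape[1]; c <- shape[2]; s <- min(shape)
    cysts <- list(
      list(center = round(c(0.31 * r, 0.31 * c)), radius = round(0.14 * s),
           intensity = 0.12),
      list(center = round(c(0.69 * r, 0.61 * c)), radius = round(0.09 * s),
           intensity = 0.20),
      list(center = round(c(0.47 * r, 0.81 * c)), radius = max(2, round(0.05 * s)),
           intensity = 0.90)
    )
  }
  if (backgroundLevel < 0 || backgroundLevel > 1)
    stop("'backgroundLevel' must lie in [0, 1]")
  stopIfNegative(textureAmplitude, "textureAmplitude")
  stopIfNegative(noiseSigma, "noiseSigma")
  for (cy in cysts) {
    if (!all(c("center", "radius", "intensity") %in% names(cy)))
      stop("each cyst needs 'center', 'radius' and 'intensity'")
    if (cy$intensity < 0 || cy$intensity > 1)
      stop("cyst intensity must lie in [0, 1]")
    lo <- cy$center - cy$radius
    hi <- cy$center + cy$radius
    if (any(lo < 1) || any(hi > shape))
      stop(sprintf("cyst at (%g, %g) with radius %g extends outside the %dx%d image",
                   cy$center[1], cy$center[2], cy$radius, shape[1], shape[2]))
  }
  structure(list(shape = shape, backgroundLevel = backgroundLevel,
                 cysts = cysts, textureAmplitude = textureAmplitude,
                 noiseModel = noiseModel, noiseSigma = noiseSigma,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' @export
print.PhantomSpec <- function(x, ...) {
  cat(sprintf("PhantomSpec: %dx%d, background %.2f, %d target(s), texture %.3g\n",
              x$shape[1], x$shape[2], x$backgroundLevel, length(x$cysts),
              x$textureAmplitude))
  cat(sprintf("  noise: %s, sigma = %.4g, seed = %d\n",
              x$noiseModel, x$noiseSigma, x$seed))
  invisible(x)
}

# smooth low-frequency texture: a few random-phase 2-D cosines, peak-scaled
.phantomTexture <- function(shape, amplitude) {
  if (amplitude == 0) return(matrix(0, shape[1], shape[2]))
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  tex <- matrix(0, shape[1], shape[2])
  for (i in 1:4) {
    fr <- stats::runif(1, 0.5, 2.5) / shape[1]
    fc <- stats::runif(1, 0.5, 2.5) / shape[2]
    ph <- stats::runif(1, 0, 2 * pi)
    tex <- tex + cos(2 * pi * (fr * r + fc * c) + ph)
  }
  tex * (amplitude / max(abs(tex)))
}

#' Generate a phantom image pair
#'
#' Renders the clean scene described by the spec and a noisy companion
#' under the spec's noise model, both clipped to [0, 1]. The generator
#' seeds its own RNG stream and restores the caller's RNG state, so the
#' same spec is bit-reproducible regardless of surrounding code.
#'
#' @param spec a [phantomSpec()] object.
#' @return list with \code{clean}, \code{noisy} (matrices in [0, 1]),
#'   \code{noise} (the raw noise field before clipping: additive deviations
#'   for Gaussian, the multiplicative field for speckle) and \code{spec}.
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(64, 64), seed = 7))
#' range(ph$clean)
#' @export
makePhantom <- function(spec) {
  if (!inherits(spec, "PhantomSpec")) spec <- do.call(phantomSpec, spec)
  withSeed(spec$seed, {
    sh <- spec$shape
    clean <- matrix(spec$backgroundLevel, sh[1], sh[2]) +
      .phantomTexture(sh, spec$textureAmplitude)
    r <- matrix(seq_len(sh[1]), sh[1], sh[2])
    c <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    for (cy in spec$cysts) {
      inside <- (r - cy$center[1])^2 + (c - cy$center[2])^2 <= cy$radius^2
      clean[inside] <- cy$intensity
    }
    clean <- clip01(clean)

    if (spec$noiseSigma == 0) {
      noise <- if (spec$noiseModel == "gaussian_additive")
        matrix(0, sh[1], sh[2]) else matrix(1, sh[1], sh[2])
      noisy <- clean
    } else if (spec$noiseModel == "gaussian_additive") {
      noise <- matrix(stats::rnorm(prod(sh), 0, spec$noiseSigma), sh[1], sh[2])
      noisy <- clip01(clean + noise)
    } else {
      # unit-mean Rayleigh field, rescaled so sd(field) = noiseSigma
      ray <- sqrt(stats::rexp(prod(sh), rate = 1)) / sqrt(pi / 4)  # mean 1
      raySd <- sqrt(4 / pi - 1)                                    # its sd
      noise <- matrix(pmax(1 + (ray - 1) * spec$noiseSigma / raySd, 0),
                      sh[1], sh[2])
      noisy <- clip01(clean * noise)
    }
    list(clean = clean, noisy = noisy, noise = noise, spec = spec)
  })
}

#' Cyst and background masks for a phantom
#'
#' Logical masks selecting the interior of every disk target and the
#' background far from all targets, for contrast-to-noise computations.
#'
#' @param spec a [phantomSpec()] object.
#' @param margin pixels of clearance between a disk and the background mask.
#' @return list with logical matrices \code{cyst} and \code{background}.
#' @export
phantomMasks <- function(spec, margin = 4) {
  if (!inherits(spec, "PhantomSpec")) stop("'spec' must be a PhantomSpec")
  sh <- spec$shape
  r <- matrix(seq_len(sh[1]), sh[1], sh[2])
  c <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  cyst <- matrix(FALSE, sh[1], sh[2])
  far <- matrix(TRUE, sh[1], sh[2])
  for (cy in spec$cysts) {
    d2 <- (r - cy$center[1])^2 + (c - cy$center[2])^2
    cyst <- cyst | (d2 <= cy$radius^2)
    far <- far & (d2 > (cy$radius + margin)^2)
  }
  list(cyst = cyst, background = far)
}
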