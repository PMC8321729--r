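# Orthonormal scaling (low-pass reconstruction) filters. The Daubechies
# coefficients are the standard published values for the extremal-phase
# family with 2 and 4 vanishing moments.
.scalingFilters <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.48296291314453416, 0.83651630373780790,
          0.22414386804201339, -0.12940952255126037),
  db4 = c(0.23037781330889650, 0.71484657055291570,
          0.63088076792985890, -0.02798376941685985,
          -0.18703481171909309, 0.03084138183556076,
          0.03288301166688520, -0.01059740178506903)
)

# quadrature mirror: g[m] = (-1)^m h[L-1-m]
.qmf <- function(h) {
  L <- length(h)
  (-1)^(0:(L - 1L)) * rev(h)
}

#' Construct a wavelet filter bank
#'
#' Builds a [Wavelet-class] object for one of the bundled orthonormal
#' families. The high-pass filter is derived from the scaling filter by the
#' quadrature-mirror relation, and the decomposition filters are the time
#' reverses of the reconstruction filters, so analysis followed by synthesis
#' is an exact inverse under every supported boundary mode.
#'
#' @param name one of \code{"haar"}, \code{"db2"}, \code{"db4"}. Daubechies
#'   db4 (8 taps) is the package default for denoising; haar gives
#'   hand-checkable coefficients.
#' @param boundary boundary extension used for finite signals:
#'   \code{"symmetric"} (default; half-sample reflection, expansive),
#'   \code{"periodic"} (circular, non-expansive, energy-preserving for
#'   even-length signals) or \code{"zero"}.
#' @return a [Wavelet-class] object.
#' @examples
#' w <- waveletFilter("haar")
#' sum(recLo(w)^2)  # orthonormal: 1
#' @export
waveletFilter <- function(name = c("db4", "haar", "db2"),
                          boundary = c("symmetric", "periodic", "zero")) {
  name <- match.arg(name)
  boundary <- match.arg(boundary)
  h <- .scalingFilters[[name]]
  g <- .qmf(h)
  new("Wavelet",
      name = name,
      decLo = rev(h), decHi = rev(g),
      recLo = h, recHi = g,
      boundary = boundary)
}

.asWavelet <- function(wavelet, boundary = NULL) {
  if (is.character(wavelet)) {
    wavelet <- waveletFilter(wavelet,
                             boundary = if (is.null(boundary)) "symmetric" else boundary)
  } else if (!is(wavelet, "Wavelet")) {
    stop("'wavelet' must be a Wavelet object or a family name")
  } else if (!is.null(boundary) && boundary != wavelet@boundary) {
    wavelet@boundary <- boundary
    validObject(wavelet)
  }
  wavelet
}

#' @describeIn waveletFilter reconstruction low-pass filter coefficients.
#' @param w a [Wavelet-class] object.
#' @export
recLo <- function(w) w@recLo

#' @describeIn waveletFilter reconstruction high-pass filter coefficients.
#' @export
recHi <- function(w) w@recHi

#' @describeIn waveletFilter decomposition low-pass filter coefficients.
#' @export
decLo <- function(w) w@decLo

#' @describeIn waveletFilter decomposition high-pass filter coefficients.
#' @export
decHi <- function(w) w@decHi

#' @describeIn waveletFilter boundary extension mode.
#' @export
boundaryMode <- function(w) w@boundary

setMethod("show", "Wavelet", function(object) {
  cat(sprintf("Wavelet filter bank '%s' (%d taps, %s boundary)\n",
              object@name, length(object@recLo), object@boundary))
  cat("  recLo:", format(object@recLo, digits = 6), "\n")
})
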