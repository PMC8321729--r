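#' @import methods
NULL

#' Wavelet filter bank
#'
#' An orthonormal two-channel filter bank together with the boundary
#' extension rule used when a finite signal is decomposed. The four filter
#' slots follow the usual analysis/synthesis convention: the decomposition
#' filters are the time-reversed reconstruction filters, and the high-pass
#' filters are the quadrature mirrors of the low-pass ones.
#'
#' @slot name wavelet family identifier, e.g. \code{"haar"}, \code{"db4"}.
#' @slot decLo,decHi numeric decomposition (analysis) filters.
#' @slot recLo,recHi numeric reconstruction (synthesis) filters.
#' @slot boundary boundary extension mode: \code{"symmetric"} (half-sample
#'   reflection), \code{"periodic"} (circular, non-expansive) or
#'   \code{"zero"} (zero padding).
#'
#' @seealso [waveletFilter()] to construct one.
#' @export
setClass("Wavelet",
  representation(
    name = "character",
    decLo = "numeric",
    decHi = "numeric",
    recLo = "numeric",
    recHi = "numeric",
    boundary = "character"
  )
)

setValidity("Wavelet", function(object) {
  msg <- character()
  L <- length(object@recLo)
  if (L < 2L || L %% 2L != 0L)
    msg <- c(msg, "filter length must be even and >= 2")
  if (length(object@recHi) != L || length(object@decLo) != L ||
      length(object@decHi) != L)
    msg <- c(msg, "all four filters must have equal length")
  if (!object@boundary %in% c("symmetric", "periodic", "zero"))
    msg <- c(msg, "boundary must be one of 'symmetric', 'periodic', 'zero'")
  # orthonormality of the low-pass filter
  if (abs(sum(object@recLo^2) - 1) > 1e-10)
    msg <- c(msg, "reconstruction low-pass filter is not unit-norm")
  if (max(abs(object@decLo - rev(object@recLo))) > 1e-12)
    msg <- c(msg, "decLo must be the time reverse of recLo")
  if (length(msg)) msg else TRUE
})

#' Multilevel 2-D wavelet coefficient set
#'
#' Container for the output of [dwt2()]: one approximation grid at the
#' coarsest level plus, for every level, three oriented detail grids
#' (horizontal, vertical, diagonal). Level 1 is the finest scale. The input
#' dimensions at each level are recorded so that [idwt2()] can reconstruct
#' an image of exactly the original size under expansive boundary modes.
#'
#' @slot levels number of decomposition levels J.
#' @slot approx numeric matrix of approximation coefficients at level J.
#' @slot details list of length J; element j is a named list with matrices
#'   \code{horizontal}, \code{vertical}, \code{diagonal} of level-j detail
#'   coefficients.
#' @slot dims list of length J of \code{c(rows, cols)}: the size of the
#'   grid that was decomposed at each level (element 1 is the original
#'   image size).
#' @slot wavelet the [Wavelet-class] used for the decomposition.
#'
#' @seealso [dwt2()], [idwt2()], [approxCoeffs()], [detailCoeffs()]
#' @export
setClass("SubbandSet",
  representation(
    levels = "integer",
    approx = "matrix",
    details = "list",
    dims = "list",
    wavelet = "Wavelet"
  )
)

setValidity("SubbandSet", function(object) {
  J <- object@levels
  if (length(J) != 1L || J < 1L) return("levels must be a positive integer")
  if (length(object@details) != J) return("details must have one entry per level")
  if (length(object@dims) != J) return("dims must have one entry per level")
  L <- length(object@wavelet@recLo)
  for (j in seq_len(J)) {
    dj <- object@details[[j]]
    if (!identical(names(dj), c("horizontal", "vertical", "diagonal")))
      return(sprintf("level %d details must be named horizontal/vertical/diagonal", j))
    expd <- vapply(object@dims[[j]], subbandLength, integer(1),
                   filterLength = L, boundary = object@wavelet@boundary)
    for (o in names(dj)) {
      if (!identical(dim(dj[[o]]), expd))
        return(sprintf("level %d %s detail grid has wrong dimensions", j, o))
    }
  }
  expd <- vapply(object@dims[[J]], subbandLength, integer(1),
                 filterLength = L, boundary = object@wavelet@boundary)
  if (!identical(dim(object@approx), expd))
    return("approximation grid has wrong dimensions")
  TRUE
})

#' Thresholding policy for wavelet shrinkage
#'
#' Bundles the shrinkage rule (hard or soft), the threshold S, and the
#' quantities it was derived from: the noise standard deviation sigma and
#' the signal length M of the universal (VisuShrink) threshold
#' S = sigma * sqrt(2 log M).
#'
#' @slot mode \code{"hard"} or \code{"soft"}.
#' @slot threshold nonnegative threshold S, in coefficient units.
#' @slot sigma noise standard deviation used to derive S (NA when S was
#'   given directly).
#' @slot m signal length (total pixel count) used to derive S (NA when S
#'   was given directly).
#' @slot sigmaSource \code{"given"} or \code{"estimated"}.
#'
#' @seealso [thresholdPolicy()], [applyThreshold()], [visuShrinkThreshold()]
#' @export
setClass("ThresholdPolicy",
  representation(
    mode = "character",
    threshold = "numeric",
    sigma = "numeric",
    m = "numeric",
    sigmaSource = "character"
  )
)

setValidity("ThresholdPolicy", function(object) {
  msg <- character()
  if (!object@mode %in% c("hard", "soft"))
    msg <- c(msg, "mode must be 'hard' or 'soft'")
  if (!is.finite(object@threshold) || object@threshold < 0)
    msg <- c(msg, "threshold must be a finite nonnegative number")
  if (!object@sigmaSource %in% c("given", "estimated"))
    msg <- c(msg, "sigmaSource must be 'given' or 'estimated'")
  if (is.finite(object@sigma) && is.finite(object@m)) {
    if (abs(object@threshold - object@sigma * sqrt(2 * log(object@m))) > 1e-12)
      msg <- c(msg, "threshold does not equal sigma * sqrt(2 * log(m))")
  }
  if (length(msg)) msg else TRUE
})

#' Detail enhancement parameters
#'
#' A linear map applied to targeted detail coefficients after thresholding:
#' every targeted coefficient c becomes gain * c + offset. gain = 1 and
#' offset = 0 is the identity. A nonzero offset is applied to every targeted
#' coefficient, including those shrunk to zero, and therefore re-introduces
#' texture into flat regions; the default is 0.
#'
#' @slot gain multiplicative gain H applied to detail coefficients.
#' @slot offset additive offset f applied to detail coefficients.
#' @slot levels integer vector of targeted levels, or empty for all levels.
#' @slot orientations subset of horizontal/vertical/diagonal to target.
#'
#' @seealso [enhanceParams()], [enhanceDetails()]
#' @export
setClass("EnhanceParams",
  representation(
    gain = "numeric",
    offset = "numeric",
    levels = "integer",
    orientations = "character"
  )
)

setValidity("EnhanceParams", function(object) {
  msg <- character()
  if (length(object@gain) != 1L || !is.finite(object@gain))
    msg <- c(msg, "gain must be a single finite number")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    msg <- c(msg, "offset must be a single finite number")
  bad <- setdiff(object@orientations, c("horizontal", "vertical", "diagonal"))
  if (length(bad))
    msg <- c(msg, paste0("unknown orientation(s): ", paste(bad, collapse = ", ")))
  if (length(object@orientations) < 1L)
    msg <- c(msg, "at least one orientation must be targeted")
  if (length(msg)) msg else TRUE
})

#' Grayscale image
#'
#' A numeric matrix of pixel intensities in [0, 1] (rows are image rows),
#' carrying the bit depth of the file it came from. Behaves as an ordinary
#' matrix everywhere; all transform functions accept either a plain matrix
#' or a \code{GrayImage}.
#'
#' @slot .Data numeric matrix with values in [0, 1].
#' @slot bitdepth \code{"8"}, \code{"16"} or \code{"float"}.
#'
#' @seealso [grayImage()], [readGrayImage()], [writeGrayImage()]
#' @export
setClass("GrayImage",
  contains = "matrix",
  representation(bitdepth = "character")
)

setValidity("GrayImage", function(object) {
  v <- object@.Data
  if (!is.numeric(v) || length(dim(v)) != 2L)
    return("pixel data must be a 2-D numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("image must contain at least one pixel")
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    return("pixel values must lie in [0, 1] with no missing values")
  if (!object@bitdepth %in% c("8", "16", "float"))
    return("bitdepth must be '8', '16' or 'float'")
  TRUE
})

#' Two-group summary statistics
#'
#' Mean, standard deviation and group size of one arm of a two-group
#' comparison, in the units the source reports (mg, days, score points).
#' Sufficient for a Welch or pooled two-sample t test; no individual-level
#' data are involved.
#'
#' @slot mean group mean.
#' @slot sd group standard deviation (> 0).
#' @slot n group size (>= 2).
#'
#' @seealso [groupSummary()], [welchTFromSummary()]
#' @export
setClass("GroupSummary",
  representation(mean = "numeric", sd = "numeric", n = "integer")
)

setValidity("GroupSummary", function(object) {
  msg <- character()
  if (length(object@mean) != 1L || !is.finite(object@mean))
    msg <- c(msg, "mean must be a single finite number")
  if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd <= 0)
    msg <- c(msg, "sd must be a single positive number")
  if (length(object@n) != 1L || object@n < 2L)
    msg <- c(msg, "n must be an integer >= 2")
  if (length(msg)) msg else TRUE
})
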