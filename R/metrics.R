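# Image quality metrics. All images are peak-1 normalized, so PSNR uses
# peak = 1.0 throughout and bit depth never enters.

#' Mean squared error between two images
#'
#' @param reference,test numeric matrices (or [GrayImage-class]) of equal
#'   dimensions.
#' @return nonnegative scalar.
#' @export
mse <- function(reference, test) {
  a <- asImageMatrix(reference, "reference")
  b <- asImageMatrix(test, "test")
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: reference is %s, test is %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' PSNR in decibels for peak-1 images: 10 log10(1 / MSE). Identical images
#' give \code{Inf}. Symmetric in its arguments.
#'
#' @inheritParams mse
#' @return PSNR in dB; \code{Inf} when the images are identical.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.5, 4, 4))  # 10*log10(4) ~= 6.0206
#' @export
psnr <- function(reference, test) {
  e <- mse(reference, test)
  if (e == 0) Inf else 10 * log10(1 / e)
}

#' Contrast-to-noise ratio between a target and the background
#'
#' |mean(background) - mean(target)| / sqrt(var(background) + var(target)),
#' the usual lesion-detectability index for cyst phantoms. Zero variance in
#' both regions with distinct means gives \code{Inf}.
#'
#' @param image numeric matrix or [GrayImage-class].
#' @param cystMask,backgroundMask disjoint, non-empty logical matrices of
#'   the image's dimensions selecting the two regions.
#' @return nonnegative scalar, possibly \code{Inf}.
#' @seealso [phantomMasks()]
#' @export
cnr <- function(image, cystMask, backgroundMask) {
  x <- asImageMatrix(image)
  for (nm in c("cystMask", "backgroundMask")) {
    m <- get(nm)
    if (!is.logical(m) || !identical(dim(m), dim(x)))
      stop(sprintf("'%s' must be a logical matrix matching the image", nm))
    if (!any(m)) stop(sprintf("'%s' selects no pixels", nm))
  }
  if (any(cystMask & backgroundMask))
    stop("cyst and background masks overlap")
  cy <- x[cystMask]
  bg <- x[backgroundMask]
  num <- abs(mean(bg) - mean(cy))
  den <- sqrt(stats::var(bg) + stats::var(cy))
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else num / den
}

#' Summarise denoising quality against a reference
#'
#' Convenience bundle of [mse()], [psnr()] and, when masks are supplied,
#' [cnr()] of the test image.
#'
#' @inheritParams mse
#' @param cystMask,backgroundMask optional region masks for the CNR.
#' @return list of class \code{"QualityReport"} with \code{mse},
#'   \code{psnr_db} and (optionally) \code{contrast_cnr}.
#' @export
qualityReport <- function(reference, test, cystMask = NULL,
                          backgroundMask = NULL) {
  rep <- list(mse = mse(reference, test), psnr_db = psnr(reference, test))
  if (!is.null(cystMask) && !is.null(backgroundMask))
    rep$contrast_cnr <- cnr(test, cystMask, backgroundMask)
  structure(rep, class = "QualityReport")
}

#' @export
print.QualityReport <- function(x, ...) {
  cat(sprintf("QualityReport: mse = %.6g, psnr = %.4g dB", x$mse, x$psnr_db))
  if (!is.null(x$contrast_cnr)) cat(sprintf(", cnr = %.4g", x$contrast_cnr))
  cat("\n")
  invisible(x)
}
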