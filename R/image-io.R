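# PNG/TIFF input and output for single-channel images, normalized to [0, 1].
# Grayscale is the native representation (B-mode ultrasound is single
# channel); RGB input is accepted only with an explicit luminance flag.
# DICOM is deliberately out of scope — convert upstream.

#' Construct a GrayImage
#'
#' @param pixels numeric matrix with values in [0, 1].
#' @param bitdepth \code{"8"}, \code{"16"} or \code{"float"}; the depth the
#'   data came from (or will be quantized to).
#' @return a [GrayImage-class].
#' @export
grayImage <- function(pixels, bitdepth = "float") {
  new("GrayImage", asImageMatrix(pixels, "pixels"),
      bitdepth = as.character(bitdepth))
}

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %dx%d, %s-bit source, range [%.4g, %.4g]\n",
              nrow(object), ncol(object), object@bitdepth,
              min(object@.Data), max(object@.Data)))
})

# Rec. 709 luminance
.luma <- function(arr) {
  0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
}

#' Read a grayscale image from PNG or TIFF
#'
#' Pixel values are scaled into [0, 1] by the file's bit depth (the readers
#' do this natively). Multi-channel files are rejected unless
#' \code{toGray = TRUE}, in which case the Rec. 709 luminance is taken; an
#' alpha channel, if present, is dropped.
#'
#' @param path file path; format is chosen by extension (.png, .tif,
#'   .tiff).
#' @param toGray convert RGB input to luminance instead of failing.
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path, toGray = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    depth <- if (!is.null(info$bit.depth)) as.character(info$bit.depth) else "8"
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(arr)
    depth <- if (!is.null(info$bits.per.sample))
      as.character(info$bits.per.sample) else "8"
  } else {
    stop(sprintf("unsupported format '.%s' (PNG and TIFF are supported)", ext))
  }
  if (!depth %in% c("8", "16")) depth <- "float"
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 2L) {
      arr <- arr[, , 1]                        # gray + alpha
    } else if (nc %in% c(3L, 4L)) {
      if (!toGray)
        stop("multi-channel image; pass toGray = TRUE to take the luminance")
      arr <- .luma(arr)
    } else {
      stop(sprintf("unsupported channel count: %d", nc))
    }
  }
  grayImage(clip01(arr), bitdepth = depth)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Values are clipped to [0, 1] and quantized to the requested depth before
#' writing, so a write/read roundtrip agrees with the in-memory image to
#' within half a quantization step. PNG output is 8-bit; TIFF supports 8 or
#' 16 bits.
#'
#' @param image numeric matrix or [GrayImage-class].
#' @param path output path (.png, .tif or .tiff).
#' @param bitdepth 8 or 16 (16 requires TIFF).
#' @return invisibly, \code{path}.
#' @export
writeGrayImage <- function(image, path, bitdepth = 8) {
  x <- clip01(asImageMatrix(image))
  bitdepth <- as.integer(bitdepth)
  if (!bitdepth %in% c(8L, 16L)) stop("'bitdepth' must be 8 or 16")
  q <- round(x * (2^bitdepth - 1)) / (2^bitdepth - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bitdepth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = bitdepth)
  } else {
    stop(sprintf("unsupported output format '.%s'", ext))
  }
  invisible(path)
}
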