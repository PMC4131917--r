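#' Calibrated grayscale image
#'
#' The unit consumed by the imaging pipeline: a rectangular 2D grid of 8-bit
#' intensities (0-255) together with a spatial calibration in micrometres per
#' pixel. All physical measurements downstream (area, Feret diameters,
#' equivalent-sphere volume) are derived from pixel counts and this scale.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`; rows are image
#'   rows (y), columns are image columns (x), origin top-left.
#' @param scale Calibration in micrometres per pixel; must be strictly
#'   positive.
#' @param source_id Free-text identifier carried into measurement tables
#'   (typically the file name).
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(140, 32, 32), scale = 1.29)
#' @export
gray_image <- function(pixels, scale, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_("`pixels` must be a numeric matrix")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop_("pixel intensities must be non-negative and non-missing")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop_("`scale` (um per pixel) must be a single positive number")
  }
  structure(
    list(pixels = pixels, scale = as.numeric(scale),
         source_id = as.character(source_id)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              if (nzchar(x$source_id)) paste0(", '", x$source_id, "'") else ""))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Read a grayscale image from PNG or TIFF
#'
#' 8- or 16-bit grayscale files are accepted; RGB files are collapsed to
#' luminance. Intensities are rescaled to the 0-255 range used internally.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param scale Micrometres per pixel (required; magnification calibration is
#'   never guessed from the file).
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, scale) {
  if (!file.exists(path)) stop_("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_("unsupported image format '.%s' (use PNG or TIFF)", ext)
  )
  if (length(dim(arr)) == 3L) {
    # collapse RGB(A) to luminance
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  gray_image(round(arr * 255), scale = scale, source_id = basename(path))
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param image A [gray_image].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  px <- pmin(pmax(image$pixels, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, target = path),
    tif = ,
    tiff = tiff::writeTIFF(px, where = path, bits.per.sample = 8L),
    stop_("unsupported image format '.%s' (use PNG or TIFF)", ext)
  )
  invisible(path)
}
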