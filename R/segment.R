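#' Equivalent-sphere radius and volume from projected area
#'
#' The spheroid's measured 2D projected area `S` determines the radius of
#' the circle of equal area, \eqn{r = \sqrt{S/\pi}}, and the volume of the
#' sphere of that radius, \eqn{V = (4/3)\pi r^3}. The estimate is approximately
#' valid for ellipsoids up to a width/length ratio of 1.5.
#'
#' @param area_S Projected area in square micrometres (> 0); vectorised.
#' @return A list with components `radius` (um) and `volume` (um^3).
#' @examples
#' equivalent_volume(pi)            # unit radius: V = 4*pi/3
#' equivalent_volume(pi * 200^2)    # a 400-um spheroid
#' @export
equivalent_volume <- function(area_S) {
  if (!is.numeric(area_S) || any(!is.finite(area_S)) || any(area_S <= 0)) {
    stop_("area must be positive and finite")
  }
  r <- sqrt(area_S / pi)
  list(radius = r, volume = (4 / 3) * pi * r^3)
}

empty_morphometry <- function(source_id, flags = character()) {
  structure(
    list(source_id = source_id, area_um2 = NA_real_, radius_um = NA_real_,
         diameter_um = NA_real_, volume_um3 = NA_real_,
         feret_max_um = NA_real_, feret_min_um = NA_real_,
         aspect_ratio = NA_real_, empty = TRUE, flags = flags,
         outline = NULL),
    class = "spheroid_morphometry"
  )
}

#' Segment a single-spheroid image and measure it
#'
#' Reproduces the automated morphometry pipeline: binarise at the Yen
#' threshold (the spheroid being the dark class for phase-contrast images),
#' remove small objects (artifact cleaning), fill holes, keep the largest
#' remaining object with a centrality tie-break (debris separation), then
#' measure area, maximum/minimum Feret diameter, equivalent radius and
#' equivalent-sphere volume. A well with no object covering at least
#' `empty_frac` of the frame is reported as empty, with all physical fields
#' `NA`.
#'
#' @param image A calibrated [gray_image].
#' @param invert If `TRUE` the spheroid is taken as the bright class
#'   (e.g. fluorescence); default is the dark class.
#' @param min_object_frac Objects smaller than this fraction of the frame
#'   are removed as artifacts before debris separation.
#' @param empty_frac Minimum object size, as a fraction of the frame, for a
#'   well to count as occupied.
#' @return A `spheroid_morphometry` object: fields `area_um2`, `radius_um`,
#'   `diameter_um`, `volume_um3`, `feret_max_um`, `feret_min_um`,
#'   `aspect_ratio`, `empty`, `flags`, and the detected boundary pixels in
#'   `outline`. `aspect_ratio > 1.5` raises the `"aspect_gt_1.5"` flag (the
#'   equivalent-sphere estimate degrades beyond that elongation).
#' @export
segment_spheroid <- function(image, invert = FALSE, min_object_frac = 0.005,
                             empty_frac = 0.01) {
  stopifnot(inherits(image, "gray_image"))
  if (image$scale <= 0) stop_("image is uncalibrated (scale <= 0)")
  px <- image$pixels
  npx <- length(px)

  # Yen's criterion sees only class masses, so its unconstrained maximum can
  # isolate a tiny intensity tail (the 1-3 px bright halo, or a few noise
  # pixels) instead of splitting body from background; the pipeline requires
  # both classes to hold at least 5% of the pixels
  thr <- tryCatch(yen_threshold(image, min_class_frac = 0.05),
                  error = function(e) NULL)
  if (is.null(thr)) {
    # constant (or near-constant) image: nothing to segment
    return(empty_morphometry(image$source_id, flags = "constant_image"))
  }
  mask <- if (invert) px > thr else px <= thr

  # empty-well guard: a well with no object shows no real intensity
  # separation between the two classes, only noise.  Median/MAD statistics
  # keep the guard insensitive to the few background-tail pixels an
  # edge-seeking cut sweeps into the dark class.
  mu_fg <- median(px[mask]); mu_bg <- median(px[!mask])
  sd_fg <- if (sum(mask) > 1) mad(px[mask]) else 0
  sd_bg <- if (sum(!mask) > 1) mad(px[!mask]) else 0
  if (!is.finite(mu_fg) || !is.finite(mu_bg) ||
      abs(mu_fg - mu_bg) <= 2 * (sd_fg + sd_bg)) {
    return(empty_morphometry(image$source_id, flags = "low_contrast"))
  }
  storage.mode(mask) <- "integer"

  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= max(1, min_object_frac * npx))
  if (length(keep) == 0L || max(sizes) < empty_frac * npx) {
    return(empty_morphometry(image$source_id))
  }
  mask2 <- matrix(as.integer(lab %in% keep), nrow(px), ncol(px))
  filled <- EBImage::fillHull(mask2)
  lab2 <- EBImage::bwlabel(filled)
  sizes2 <- tabulate(lab2[lab2 > 0])
  best <- which(sizes2 == max(sizes2))
  if (length(best) > 1L) {
    # size tie: prefer the object whose centroid is nearest the frame centre
    cx <- (ncol(px) + 1) / 2; cy <- (nrow(px) + 1) / 2
    d2 <- vapply(best, function(id) {
      w <- which(lab2 == id, arr.ind = TRUE)
      (mean(w[, 2]) - cx)^2 + (mean(w[, 1]) - cy)^2
    }, numeric(1))
    best <- best[which.min(d2)]
  }
  obj <- lab2 == best
  if (sum(obj) < empty_frac * npx) {
    return(empty_morphometry(image$source_id))
  }

  idx <- which(obj, arr.ind = TRUE)            # (row, col) = (y, x)
  coords <- cbind(x = idx[, 2], y = idx[, 1])
  area_px <- nrow(coords)
  area_um2 <- area_px * image$scale^2
  eq <- equivalent_volume(area_um2)
  fer <- feret_diameters(coords) * image$scale
  aspect <- unname(fer["max"] / fer["min"])
  flags <- character()
  if (aspect > 1.5) flags <- "aspect_gt_1.5"

  # boundary pixels: object pixels with at least one 4-neighbour outside
  padded <- matrix(FALSE, nrow(px) + 2L, ncol(px) + 2L)
  padded[2:(nrow(px) + 1L), 2:(ncol(px) + 1L)] <- obj
  inner <- padded[2:(nrow(px) + 1L), 2:(ncol(px) + 1L)] &
    padded[1:nrow(px), 2:(ncol(px) + 1L)] &
    padded[3:(nrow(px) + 2L), 2:(ncol(px) + 1L)] &
    padded[2:(nrow(px) + 1L), 1:ncol(px)] &
    padded[2:(nrow(px) + 1L), 3:(ncol(px) + 2L)]
  bidx <- which(obj & !inner, arr.ind = TRUE)

  structure(
    list(source_id = image$source_id, area_um2 = area_um2,
         radius_um = eq$radius, diameter_um = 2 * eq$radius,
         volume_um3 = eq$volume,
         feret_max_um = unname(fer["max"]), feret_min_um = unname(fer["min"]),
         aspect_ratio = aspect, empty = FALSE, flags = flags,
         outline = cbind(x = bidx[, 2], y = bidx[, 1])),
    class = "spheroid_morphometry"
  )
}

#' @export
print.spheroid_morphometry <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<spheroid_morphometry> '%s': EMPTY well%s\n", x$source_id,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  } else {
    cat(sprintf(
      "<spheroid_morphometry> '%s': area %.0f um^2, d_eq %.1f um, V %.3g um^3, Feret %.1f/%.1f um (AR %.2f)%s\n",
      x$source_id, x$area_um2, x$diameter_um, x$volume_um3,
      x$feret_max_um, x$feret_min_um, x$aspect_ratio,
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.spheroid_morphometry <- function(x, ...) {
  data.frame(
    source_id = x$source_id, area_um2 = x$area_um2, radius_um = x$radius_um,
    diameter_um = x$diameter_um, volume_um3 = x$volume_um3,
    feret_max_um = x$feret_max_um, feret_min_um = x$feret_min_um,
    aspect_ratio = x$aspect_ratio, empty = x$empty,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
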