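#' Ground truth for a synthetic spheroid image
#'
#' Describes one synthetic phase-contrast-like image of a single spheroid:
#' an elliptical body with known centre, semi-axes and orientation, optional
#' debris specks, and additive Gaussian pixel noise. The truth record is
#' sufficient to score any downstream measurement without external reference
#' (`true_area()` gives the exact projected area in pixels squared).
#'
#' @param semi_axes Numeric pair `c(a, b)` of ellipse semi-axes in pixels,
#'   with `a >= b > 0`.
#' @param dim Image dimensions `c(rows, cols)` in pixels. Default frames the
#'   body with a comfortable margin.
#' @param center Body centre `c(x, y)` in pixel coordinates (x = column,
#'   y = row); defaults to the image centre, mirroring the centrally
#'   positioned spheroid a round-bottom ULA well produces.
#' @param orientation Major-axis angle in radians.
#' @param scale Micrometres per pixel.
#' @param debris_count Number of small dark debris discs placed disjoint from
#'   the body.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (8-bit units).
#' @param seed Integer seed; identical truths generate bit-identical images.
#' @return An object of class `image_truth`.
#' @seealso [generate_spheroid_image()], [generate_empty_well_image()]
#' @export
image_truth <- function(semi_axes, dim = NULL, center = NULL,
                        orientation = 0, scale = 1, debris_count = 0L,
                        noise_sd = 0, seed = 1L) {
  a <- semi_axes[1]; b <- semi_axes[2]
  if (!(is.finite(a) && is.finite(b) && a >= b && b > 0)) {
    stop_("semi-axes must satisfy a >= b > 0")
  }
  if (debris_count < 0) stop_("debris_count must be >= 0")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  if (scale <= 0) stop_("scale must be positive")
  if (is.null(dim)) dim <- rep(2L * ceiling(a) + 64L, 2L)
  if (is.null(center)) center <- c(dim[2] / 2, dim[1] / 2)
  structure(
    list(center = as.numeric(center), semi_axes = as.numeric(c(a, b)),
         orientation = as.numeric(orientation), scale = as.numeric(scale),
         debris_count = as.integer(debris_count),
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed),
         dim = as.integer(dim)),
    class = "image_truth"
  )
}

#' @export
print.image_truth <- function(x, ...) {
  cat(sprintf(
    "<image_truth> a=%.1f b=%.1f px (aspect %.3f), %dx%d px, %d debris, noise_sd=%.1f, seed=%d\n",
    x$semi_axes[1], x$semi_axes[2], aspect_ratio(x), x$dim[1], x$dim[2],
    x$debris_count, x$noise_sd, x$seed))
  invisible(x)
}

#' True projected area of a synthetic body, in pixels squared
#' @param truth An [image_truth].
#' @export
true_area <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  pi * truth$semi_axes[1] * truth$semi_axes[2]
}

#' Width/length aspect ratio of a synthetic body
#' @param truth An [image_truth].
#' @export
aspect_ratio <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  truth$semi_axes[1] / truth$semi_axes[2]
}

# Intensity levels of the synthetic phase-contrast rendering.  The
# segmentation contract depends only on contrast polarity (dark body on a
# lighter background with a bright halo), so the absolute levels are fixed
# constants of the generator.
.SYN <- list(background = 140, body = 60, rim = 200, debris = 55,
             rim_width = 2, debris_gap = 4)

ellipse_metric <- function(xg, yg, cx, cy, a, b, theta) {
  dx <- xg - cx; dy <- yg - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

#' Generate a synthetic single-spheroid image
#'
#' Renders a phase-contrast-like image from its ground truth: a dark
#' elliptical body with a brighter halo on a mid-gray background, optional
#' small dark debris discs that never touch the body, and additive Gaussian
#' noise, quantised to 8 bits. The same truth (same seed) always yields a
#' byte-identical image.
#'
#' @param truth An [image_truth]. The body (including halo) must fit in the
#'   frame with a margin of at least 3 pixels.
#' @return A [gray_image] carrying `truth` as attribute `"truth"`.
#' @examples
#' img <- generate_spheroid_image(image_truth(c(60, 40), seed = 7))
#' @export
generate_spheroid_image <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  nr <- truth$dim[1]; nc <- truth$dim[2]
  a <- truth$semi_axes[1]; b <- truth$semi_axes[2]
  th <- truth$orientation
  cx <- truth$center[1]; cy <- truth$center[2]
  rw <- .SYN$rim_width
  # half-extents of the rotated ellipse bounding box, halo included
  ex <- sqrt(((a + rw) * cos(th))^2 + ((b + rw) * sin(th))^2)
  ey <- sqrt(((a + rw) * sin(th))^2 + ((b + rw) * cos(th))^2)
  if (cx - ex < 4 || cx + ex > nc - 3 || cy - ey < 4 || cy + ey > nr - 3) {
    stop_("ellipse (with halo) does not fit in a %dx%d frame with a 3 px margin",
          nr, nc)
  }
  xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  yg <- matrix(seq_len(nr), nr, nc)
  m_body <- ellipse_metric(xg, yg, cx, cy, a, b, th) <= 1
  m_halo <- ellipse_metric(xg, yg, cx, cy, a + rw, b + rw, th) <= 1 & !m_body

  px <- matrix(.SYN$background, nr, nc)
  px[m_halo] <- .SYN$rim
  px[m_body] <- .SYN$body

  with_seed(truth$seed, {
    placed <- 0L; attempts <- 0L
    deb <- list()
    while (placed < truth$debris_count && attempts < 200L * max(1L, truth$debris_count)) {
      attempts <- attempts + 1L
      r <- runif(1, 3, 10)
      dx0 <- runif(1, r + 4, nc - r - 3)
      dy0 <- runif(1, r + 4, nr - r - 3)
      # keep the speck clear of the body: its centre must lie outside the
      # ellipse dilated by the speck radius, the halo and a safety gap
      pad <- r + rw + .SYN$debris_gap
      if (ellipse_metric(dx0, dy0, cx, cy, a + pad, b + pad, th) <= 1) next
      clash <- FALSE
      for (d in deb) {
        if ((dx0 - d[1])^2 + (dy0 - d[2])^2 < (r + d[3] + 2)^2) clash <- TRUE
      }
      if (clash) next
      px[(xg - dx0)^2 + (yg - dy0)^2 <= r^2] <- .SYN$debris
      deb[[length(deb) + 1L]] <- c(dx0, dy0, r)
      placed <- placed + 1L
    }
    if (truth$noise_sd > 0) {
      px <- px + rnorm(length(px), 0, truth$noise_sd)
    }
  })
  px <- round(pmin(pmax(px, 0), 255))
  out <- gray_image(px, scale = truth$scale,
                    source_id = sprintf("synthetic_spheroid_seed%d", truth$seed))
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic empty-well image
#'
#' Background texture only, with no spheroid-scale object; used to exercise
#' the segmentation pipeline's empty-well reporting.
#'
#' @param noise_sd Additive Gaussian noise SD (8-bit units).
#' @param seed Integer seed.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param scale Micrometres per pixel.
#' @return A [gray_image].
#' @export
generate_empty_well_image <- function(noise_sd = 5, seed = 1L,
                                      dim = c(256L, 256L), scale = 1) {
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  px <- matrix(.SYN$background, dim[1], dim[2])
  if (noise_sd > 0) {
    px <- with_seed(seed, px + rnorm(length(px), 0, noise_sd))
  }
  px <- round(pmin(pmax(px, 0), 255))
  gray_image(px, scale = scale,
             source_id = sprintf("synthetic_empty_seed%d", seed))
}

#' Draw a randomised spheroid-image truth
#'
#' Samples one ground truth from the validation envelope: equivalent
#' diameter uniform over `diameter_range`, width/length aspect ratio
#' uniform in `[1, 1.5]` (the validity bound of the equivalent-sphere
#' estimate), random orientation, noise SD uniform up to `max_noise_sd`,
#' and a uniform number of debris specks up to `max_debris`. Deterministic
#' in `seed`.
#'
#' @param seed Integer seed driving every sampled property.
#' @param diameter_range Major-axis diameter range, pixels.
#' @param max_noise_sd Upper bound for the additive noise SD.
#' @param max_debris Upper bound for the debris count.
#' @param scale Micrometres per pixel.
#' @return An [image_truth].
#' @export
sample_image_truth <- function(seed, diameter_range = c(150, 800),
                               max_noise_sd = 10, max_debris = 20,
                               scale = 1) {
  with_seed(seed, {
    d <- runif(1, diameter_range[1], diameter_range[2])
    ar <- runif(1, 1, 1.5)
    a <- d / 2
    b <- a / ar
    image_truth(c(a, b), orientation = runif(1, 0, pi), scale = scale,
                debris_count = sample.int(max_debris + 1L, 1L) - 1L,
                noise_sd = runif(1, 0, max_noise_sd), seed = seed)
  })
}
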