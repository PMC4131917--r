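#' Yen's maximum-correlation threshold
#'
#' Computes the global intensity threshold of Yen's maximum-correlation
#' criterion on the 256-bin (8-bit) histogram. For a candidate cut `t`
#' splitting the normalised histogram into classes `{i <= t}` and `{i > t}`,
#' the criterion is
#' \deqn{TC(t) = -\ln[G_1(t)\,G_2(t)] + 2\ln[P(t)(1 - P(t))]}
#' where \eqn{G_1, G_2} are the within-class sums of squared bin
#' probabilities and \eqn{P} the cumulative probability. The returned
#' threshold is the intensity maximising `TC`; when a contiguous run of cuts
#' ties (e.g. a two-level histogram), the middle cut of the run is returned,
#' so the threshold always falls between the populated levels. The result
#' depends on the histogram only, never on image size.
#'
#' @param image A [gray_image], a numeric matrix/vector of intensities in
#'   `[0, 255]`, or a length-256 vector of histogram counts (named use via
#'   `counts = TRUE`).
#' @param counts If `TRUE`, `image` is interpreted as a length-256 vector of
#'   histogram counts for intensities 0..255.
#' @param min_class_frac Minimum probability mass required on each side of
#'   the cut. The default 0 is the plain criterion maximum. A positive value
#'   guards pipeline use against a degeneracy of entropic thresholds on
#'   quasi-discrete histograms, where the maximising cut isolates a tiny
#'   intensity tail (e.g. a 1-3 px bright halo) instead of splitting the two
#'   dominant classes.
#' @return The threshold intensity (0-254). Pixels with intensity `<=` the
#'   threshold form one class (the dark class), `>` the other.
#' @references Yen, Chang & Chang (1995), IEEE Trans. Image Processing 4(3).
#' @examples
#' h <- numeric(256); h[11] <- 50; h[201] <- 50
#' yen_threshold(h, counts = TRUE)   # between 10 and 200
#' @export
yen_threshold <- function(image, counts = FALSE, min_class_frac = 0) {
  if (inherits(image, "gray_image")) {
    v <- image$pixels
  } else {
    v <- image
  }
  if (isTRUE(counts)) {
    if (length(v) != 256L) stop_("histogram counts must have length 256")
    h <- as.numeric(v)
  } else {
    v <- round(pmin(pmax(as.numeric(v), 0), 255))
    h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  }
  if (sum(h > 0) < 2L) {
    stop_("constant image: no threshold exists")
  }
  p <- h / sum(h)
  P <- cumsum(p)
  G1 <- cumsum(p^2)
  G2 <- sum(p^2) - G1
  # candidate cuts t = 0..254 (index 1..255)
  i <- seq_len(255L)
  crit <- rep(-Inf, 255L)
  ok <- P[i] >= max(min_class_frac, .Machine$double.xmin) &
    (1 - P[i]) >= max(min_class_frac, .Machine$double.xmin) &
    G1[i] > 0 & G2[i] > 0
  if (!any(ok)) {
    stop_("no cut leaves at least %.0f%% of pixels in each class",
          100 * min_class_frac)
  }
  crit[ok] <- -log(G1[i][ok] * G2[i][ok]) + 2 * log(P[i][ok] * (1 - P[i][ok]))
  ties <- which(crit == max(crit))
  # middle of the maximal plateau; cuts through empty bins are equivalent
  ties[ceiling(length(ties) / 2)] - 1L
}
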