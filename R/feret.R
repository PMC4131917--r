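# Feret (caliper) diameters of a pixel object, computed over the convex
# hull of its pixel centres.  One pixel is added to both calipers to account
# for the unit footprint of boundary pixels, so a digital disc of radius r
# measures ~2r rather than 2r - 1.
feret_diameters <- function(coords) {
  if (nrow(coords) == 1L) {
    return(c(max = 1, min = 1))
  }
  hull <- coords[chull(coords), , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) {
    d <- sqrt(sum((hull[1, ] - hull[nrow(hull), ])^2))
    return(c(max = d + 1, min = 1))
  }
  dmax <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (hull[(i + 1L):n, 1] - hull[i, 1])^2 +
          (hull[(i + 1L):n, 2] - hull[i, 2])^2
    dmax <- max(dmax, max(d2))
  }
  dmax <- sqrt(dmax)
  # minimum width: for a convex polygon the minimum caliper distance is
  # attained perpendicular to one of its edges (rotating calipers)
  wmin <- Inf
  for (i in seq_len(n)) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) next
    # perpendicular distance of every hull vertex from the edge line
    d <- abs((hull[, 1] - p1[1]) * e[2] - (hull[, 2] - p1[2]) * e[1]) / len
    wmin <- min(wmin, max(d))
  }
  c(max = dmax + 1, min = wmin + 1)
}
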