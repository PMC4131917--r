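# Independent oracles used across the suite.

# Brute-force Yen threshold: evaluates the maximum-correlation criterion at
# every candidate cut with plain loops, no shared code with yen_threshold().
yen_bruteforce <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf
  best_t <- integer(0)
  for (t in 0:254) {
    P <- sum(p[1:(t + 1)])
    if (P <= 0 || P >= 1) next
    G1 <- sum(p[1:(t + 1)]^2)
    G2 <- sum(p[(t + 2):256]^2)
    if (G1 <= 0 || G2 <= 0) next
    tc <- -log(G1 * G2) + 2 * log(P * (1 - P))
    if (tc > best) {
      best <- tc
      best_t <- t
    } else if (tc == best) {
      best_t <- c(best_t, t)
    }
  }
  # same tie rule as the implementation: middle cut of the maximal plateau
  best_t[ceiling(length(best_t) / 2)]
}

# Monte-Carlo power oracle: simulates two-sample one-tailed Welch-free
# (pooled) t-tests at the stated design and counts rejections.
mc_power_oracle <- function(drop, cv, n, alpha, nsim, seed) {
  set.seed(seed)
  sd1 <- cv
  sd2 <- cv * (100 - drop) / 100
  ctrl <- matrix(rnorm(nsim * n, 100, sd1), nsim, n)
  trt <- matrix(rnorm(nsim * n, 100 - drop, sd2), nsim, n)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(trt)
  v1 <- apply(ctrl, 1, var); v2 <- apply(trt, 1, var)
  sp <- sqrt((v1 + v2) / 2)
  tstat <- (m1 - m2) / (sp * sqrt(2 / n))
  mean(tstat > qt(1 - alpha, 2 * n - 2))
}

# Two-class synthetic disk with no halo: the direct Yen use case.  The
# default frame balances the two class masses (disk covers ~50% of pixels),
# where the criterion's cut falls beside the inter-class valley.
make_plain_disk <- function(radius, dim = round(radius * 2.5), body = 60,
                            background = 170, noise_sd = 0, seed = 1) {
  xg <- matrix(seq_len(dim), dim, dim, byrow = TRUE)
  yg <- matrix(seq_len(dim), dim, dim)
  cx <- (dim + 1) / 2
  inside <- (xg - cx)^2 + (yg - cx)^2 <= radius^2
  px <- matrix(background, dim, dim)
  px[inside] <- body
  if (noise_sd > 0) {
    set.seed(seed)
    px <- px + rnorm(length(px), 0, noise_sd)
  }
  list(image = gray_image(round(pmin(pmax(px, 0), 255)), scale = 1),
       mask = inside)
}

# Extra-sum-of-squares F-test between two nested dr_fit objects
# (full = biphasic, reduced = 4PL) fitted to the same points.
nested_ftest <- function(reduced, full) {
  ddf <- reduced$df - full$df
  f <- ((reduced$ss_residual - full$ss_residual) / ddf) /
    (full$ss_residual / full$df)
  pf(max(f, 0), ddf, full$df, lower.tail = FALSE)
}
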