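#' Robust FDR-based outlier detection for plate readings
#'
#' A location-model variant of the robust-regression-and-outlier-removal
#' (ROUT) idea: residuals are taken from the median, a robust scale is
#' estimated as the 68.27th percentile of the absolute residuals (the RSDR
#' analogue; it matches the SD on clean normal data), each value gets a
#' t-like score, and outliers are flagged by a Benjamini-Hochberg false
#' discovery step at rate `q_percent`. On clean data the expected flagged
#' fraction is at most about `q_percent`; constant data flags nothing.
#'
#' @param values Numeric vector, length >= 5.
#' @param q_percent Target false discovery rate, in percent (default 1).
#' @return Integer indices of the flagged values (possibly empty).
#' @export
detect_outliers_robust <- function(values, q_percent = 1) {
  n <- length(values)
  if (n < 5L) stop_("need at least 5 values for robust outlier detection")
  if (q_percent <= 0 || q_percent >= 100) stop_("q_percent must be in (0, 100)")
  res <- values - median(values)
  scale <- unname(quantile(abs(res), 0.6827, names = FALSE))
  if (scale == 0) {
    big <- which(abs(res) > 0)
    return(as.integer(big))   # identical values can never be outliers
  }
  tt <- res / scale
  p <- 2 * pt(-abs(tt), df = n - 1L)
  ord <- order(p)
  thresh <- (q_percent / 100) * seq_len(n) / n
  k <- which(p[ord] <= thresh)
  if (length(k) == 0L) return(integer(0))
  sort(ord[seq_len(max(k))])
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into `K2 = Z_skew^2 + Z_kurt^2`, referred to a
#' chi-square distribution with 2 degrees of freedom. The small-sample
#' transformations require `n >= 20`.
#'
#' @param values Numeric vector, `n >= 20`.
#' @return A list with `k2`, `p`, and the component statistics `z_skew`,
#'   `z_kurt`.
#' @export
dagostino_k2 <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 20L) stop_("D'Agostino-Pearson K2 requires n >= 20")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_("zero variance: normality test undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino's Z1
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn's Z2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Power of a t-test to detect a viability drop at a given plate CV
#'
#' Computes the power of a t-test to detect a `drop_percent` reduction in
#' mean viability when well-to-well variability is `cv_percent`. In the
#' default two-sample design the control group has mean 100 and SD equal to
#' the CV, the treated group mean `100 - drop` with SD proportional to its
#' mean (both groups carry the plate CV), and power comes from the
#' noncentral-t distribution with the pooled SD and `n` replicates per
#' group. A one-sample design (a sample of `n` treated wells against the
#' known plate mean) is available via `design`.
#'
#' @param drop_percent True percent drop in mean viability, in (0, 100).
#' @param cv_percent Plate coefficient of variation, in percent (> 0).
#' @param n_per_group Replicates per group (>= 2).
#' @param alpha Significance level, in (0, 0.5].
#' @param tails `"one"` or `"two"`.
#' @param design `"two.sample"` (default) or `"one.sample"`.
#' @return Power `1 - beta` in `[0, 1]`.
#' @examples
#' detection_power(20, 15, 6)  # ~0.77
#' detection_power(20, 9, 6)   # ~0.99
#' @export
detection_power <- function(drop_percent, cv_percent, n_per_group,
                            alpha = 0.05, tails = c("one", "two"),
                            design = c("two.sample", "one.sample")) {
  tails <- match.arg(tails)
  design <- match.arg(design)
  if (drop_percent <= 0 || drop_percent >= 100) {
    stop_("drop_percent must be in (0, 100)")
  }
  if (cv_percent <= 0) stop_("cv_percent must be positive")
  if (n_per_group < 2) stop_("n_per_group must be >= 2")
  if (alpha <= 0 || alpha > 0.5) stop_("alpha must be in (0, 0.5]")
  sd_ctrl <- cv_percent
  sd_trt <- cv_percent * (100 - drop_percent) / 100
  if (design == "two.sample") {
    sp <- sqrt((sd_ctrl^2 + sd_trt^2) / 2)
    df <- 2 * n_per_group - 2
    ncp <- drop_percent / (sp * sqrt(2 / n_per_group))
  } else {
    df <- n_per_group - 1
    ncp <- drop_percent / (sd_trt / sqrt(n_per_group))
  }
  if (tails == "one") {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
}

#' Plate uniformity report
#'
#' Summarises within-plate uniformity of a morphometric readout (diameter
#' or volume): robust outlier removal, mean and CV of the cleaned values,
#' the D'Agostino-Pearson K2 normality verdict, and the power of a
#' one-tailed t-test with `n_replicates` per group to detect a
#' `drop_percent` viability drop at the observed CV.
#'
#' @param values Numeric readings for all wells of the plate.
#' @param q_percent FDR for outlier removal, percent.
#' @param drop_percent Effect size for the power computation, percent.
#' @param n_replicates Replicates per condition in the downstream screen.
#' @param alpha Significance level for the power computation.
#' @return An object of class `uniformity_report`.
#' @export
plate_uniformity <- function(values, q_percent = 1, drop_percent = 20,
                             n_replicates = 6, alpha = 0.05) {
  out_idx <- detect_outliers_robust(values, q_percent)
  clean <- if (length(out_idx)) values[-out_idx] else values
  cv <- cv_percent(clean)
  k2 <- if (length(clean) >= 20L) dagostino_k2(clean) else
    list(k2 = NA_real_, p = NA_real_)
  pw <- detection_power(drop_percent, cv, n_replicates, alpha, "one")
  structure(
    list(n_wells = length(values), n_outliers = length(out_idx),
         outlier_ids = out_idx, mean = mean(clean), cv_percent = cv,
         k2_statistic = k2$k2, k2_p = k2$p, power_1_minus_beta = pw,
         drop_percent = drop_percent, n_replicates = n_replicates,
         alpha = alpha),
    class = "uniformity_report"
  )
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat("Plate uniformity report\n")
  cat(sprintf("  wells: %d (%d outlier%s removed at Q)\n", x$n_wells,
              x$n_outliers, if (x$n_outliers == 1) "" else "s"))
  cat(sprintf("  mean: %.4g   CV: %.2f%% (acceptance < 20%%)\n",
              x$mean, x$cv_percent))
  if (is.finite(x$k2_statistic)) {
    cat(sprintf("  D'Agostino-Pearson K2: %.3f (p = %.3g) -> %s\n",
                x$k2_statistic, x$k2_p,
                if (x$k2_p > 0.05) "consistent with normality" else
                  "non-normal"))
  }
  cat(sprintf(
    "  power (one-tailed t, n = %d/group, alpha = %.2g) to detect a %g%% drop: %.1f%%\n",
    x$n_replicates, x$alpha, x$drop_percent, 100 * x$power_1_minus_beta))
  invisible(x)
}
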