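#' Summary statistics of a group of well readings
#'
#' @param x Numeric vector of readings (length >= 2), or a list/object with
#'   components `mean`, `sd`, `n`.
#' @return An object of class `summary_stats` with fields `mean`, `sd`, `n`.
#' @export
summary_stats <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.numeric(x)) {
    if (length(x) < 2L) stop_("need at least 2 readings")
    out <- list(mean = mean(x), sd = sd(x), n = length(x))
  } else if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    out <- x[c("mean", "sd", "n")]
  } else {
    stop_("cannot interpret input as summary statistics")
  }
  if (out$sd < 0 || out$n < 2) stop_("invalid summary statistics (sd < 0 or n < 2)")
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> mean %.4g, sd %.4g, n %d\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Z-factor (screening-window coefficient)
#'
#' `Z = 1 - 3 (sd_s + sd_c) / |mean_s - mean_c|`. With sample wells against
#' a media-only control this is the Z-factor; applied to positive versus
#' negative controls the identical formula is the Z'-factor. `Z <= 1`
#' always, with equality exactly when both SDs vanish; assays with
#' `Z > 0.4` meet the screening acceptance criterion.
#'
#' @param sample,control Numeric vectors of readings or [summary_stats()].
#' @return The Z-factor (dimensionless).
#' @references Zhang, Chung & Oldenburg (1999), J. Biomol. Screen. 4(2).
#' @export
z_factor <- function(sample, control) {
  s <- summary_stats(sample); c <- summary_stats(control)
  if (s$mean == c$mean) stop_("sample and control means are equal: Z undefined")
  1 - 3 * (s$sd + c$sd) / abs(s$mean - c$mean)
}

#' Signal window
#'
#' `SW = (|mean_h - mean_l| - 3 (sd_h + sd_l)) / sd_h`, the control
#' separation left after three SDs of each group, in units of the high
#' signal's SD. Assays with `SW > 2` meet the screening acceptance
#' criterion.
#'
#' @param high,low Readings (vectors or [summary_stats()]) of the high- and
#'   low-signal groups; `sd` of the high group must be positive.
#' @return The signal window (dimensionless).
#' @export
signal_window <- function(high, low) {
  h <- summary_stats(high); l <- summary_stats(low)
  if (h$sd <= 0) stop_("high-signal sd must be positive")
  (abs(h$mean - l$mean) - 3 * (h$sd + l$sd)) / h$sd
}

#' Coefficient of variation, in percent
#'
#' `CV% = 100 sd / mean`; plate acceptance requires `CV < 20%`.
#'
#' @param x Readings (vector or [summary_stats()]); mean must be nonzero.
#' @return CV in percent.
#' @export
cv_percent <- function(x) {
  s <- summary_stats(x)
  if (s$mean == 0) stop_("mean is zero: CV undefined")
  100 * s$sd / s$mean
}

#' Relative spheroid volume increase, in percent
#'
#' `V_increase% = (V_day7 - V_day1) * 100 / V_day1`. Vectorised.
#'
#' @param v_day1,v_day7 Volumes (same units); `v_day1` must be positive.
#' @return Percent increase.
#' @export
growth_increase <- function(v_day1, v_day7) {
  if (any(!is.finite(v_day1)) || any(v_day1 <= 0)) {
    stop_("day-1 volume must be positive")
  }
  (v_day7 - v_day1) * 100 / v_day1
}

#' Residual drug fraction after medium exchanges
#'
#' Each exchange of `exchanged_volume` out of `well_volume` dilutes the
#' dissolved drug by `(well - exchanged) / well`; `n_exchanges` repeats
#' compound. Two 150-ul exchanges in a 200-ul well leave 1/16 of the
#' initial concentration.
#'
#' @param well_volume Total well volume (ul).
#' @param exchanged_volume Volume removed and replaced per exchange (ul);
#'   `0 < exchanged_volume <= well_volume`.
#' @param n_exchanges Non-negative integer count of exchanges.
#' @return The remaining fraction of the initial concentration.
#' @examples
#' residual_fraction(200, 150, 2)  # 1/16
#' @export
residual_fraction <- function(well_volume, exchanged_volume, n_exchanges) {
  if (exchanged_volume <= 0 || exchanged_volume > well_volume) {
    stop_("need 0 < exchanged_volume <= well_volume")
  }
  if (n_exchanges < 0 || n_exchanges != round(n_exchanges)) {
    stop_("n_exchanges must be a non-negative integer")
  }
  ((well_volume - exchanged_volume) / well_volume)^n_exchanges
}

#' Linear normalisation between two anchor levels
#'
#' Maps `low -> 0` and `high -> 100` linearly; values outside the anchors
#' are not clipped.
#'
#' @param values Numeric vector of raw readings.
#' @param low,high Anchor means; must differ.
#' @return Values on the percent scale.
#' @export
normalize_to_anchors <- function(values, low, high) {
  if (!is.finite(low) || !is.finite(high) || low == high) {
    stop_("anchor means must be finite and distinct")
  }
  100 * (values - low) / (high - low)
}

#' Normalise plate readings to a percent scale
#'
#' Two schemes are supported. `"cytotoxicity"`: the untreated (negative,
#' vehicle) control mean defines 100% viability and the positive (killed)
#' control mean 0%. `"validation"`: the highest reading on the plate
#' defines 100% and the mean of cell-free media-only wells 0%.
#'
#' @param readings Data frame with columns `reading` and `role` (values
#'   `sample`, `negative_control`, `positive_control`, `media_only`).
#' @param scheme `"cytotoxicity"` or `"validation"`.
#' @return `readings` with an added `viability_pct` column.
#' @export
normalize_readings <- function(readings,
                               scheme = c("cytotoxicity", "validation")) {
  scheme <- match.arg(scheme)
  if (!all(c("reading", "role") %in% names(readings))) {
    stop_("`readings` must have columns 'reading' and 'role'")
  }
  if (scheme == "cytotoxicity") {
    hi <- readings$reading[readings$role == "negative_control"]
    lo <- readings$reading[readings$role == "positive_control"]
    if (length(hi) == 0L || length(lo) == 0L) {
      stop_("cytotoxicity normalisation needs negative and positive control wells")
    }
    high <- mean(hi); low <- mean(lo)
  } else {
    lo <- readings$reading[readings$role == "media_only"]
    if (length(lo) == 0L) {
      stop_("validation normalisation needs media-only wells")
    }
    low <- mean(lo)
    high <- max(readings$reading[readings$role != "media_only"])
  }
  readings$viability_pct <- normalize_to_anchors(readings$reading, low, high)
  readings
}

#' Per-condition assay quality against screening acceptance criteria
#'
#' For each sample condition on a plate, computes the Z'-factor and signal
#' window against a chosen control and the CV of the raw readings (CV is
#' always computed pre-normalisation), together with pass flags for the
#' acceptance criteria Z > 0.4, SW > 2 and CV < 20%.
#'
#' @param readings Data frame with columns `reading`, `role`, `condition`
#'   (e.g. from [read_plate_csv()] or [simulate_plate()]).
#' @param control Role used as the low/control group.
#' @return A data frame, one row per condition, of class `qc_report`.
#' @export
plate_qc <- function(readings,
                     control = c("positive_control", "media_only",
                                 "negative_control")) {
  control <- match.arg(control)
  ctrl <- readings$reading[readings$role == control]
  if (length(ctrl) < 2L) stop_("need >= 2 wells with role '%s'", control)
  conds <- unique(readings$condition[readings$role == "sample"])
  rows <- lapply(conds, function(cd) {
    v <- readings$reading[readings$role == "sample" & readings$condition == cd]
    if (length(v) < 2L) return(NULL)
    hi <- if (mean(v) >= mean(ctrl)) v else ctrl
    lo <- if (mean(v) >= mean(ctrl)) ctrl else v
    z <- tryCatch(z_factor(v, ctrl), error = function(e) NA_real_)
    sw <- tryCatch(signal_window(hi, lo), error = function(e) NA_real_)
    cv <- tryCatch(cv_percent(v), error = function(e) NA_real_)
    data.frame(condition = cd, n = length(v), mean = mean(v), sd = sd(v),
               z_factor = z, signal_window = sw, cv_percent = cv,
               pass_z = !is.na(z) & z > 0.4,
               pass_sw = !is.na(sw) & sw > 2,
               pass_cv = !is.na(cv) & cv < 20,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", class(out))
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Assay quality report (acceptance: Z > 0.4, SW > 2, CV < 20%)\n")
  y <- x
  class(y) <- "data.frame"
  y$z_factor <- round(y$z_factor, 3)
  y$signal_window <- round(y$signal_window, 2)
  y$cv_percent <- round(y$cv_percent, 2)
  y$mean <- signif(y$mean, 5)
  y$sd <- signif(y$sd, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
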