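#' Combine IC50 determinations across experimental runs
#'
#' Three procedures for deriving one IC50 from several independent runs of
#' the same assay, all operating on the log10 scale (logIC50 distributions
#' are closer to normal than raw IC50s):
#'
#' * `"pooled"`: concatenate all points and fit a single curve.
#' * `"geometric_mean"`: average the per-run logIC50s; the combined IC50 is
#'   `10^mean(logIC50)`, i.e. the geometric mean of the run IC50s, with a
#'   t-based 95% CI on the log scale.
#' * `"shared_ftest"`: refit all runs jointly with every parameter free per
#'   run except a single shared logIC50, and compare against the separate
#'   fits with the extra-sum-of-squares F-test
#'   `F = ((SS_shared - SS_sep) / (df_shared - df_sep)) / (SS_sep / df_sep)`.
#'   A small p-value means the runs' IC50s are statistically different and
#'   the shared estimate should be interpreted with care (the
#'   `different_runs` flag).
#'
#' @param runs A list of `dr_fit` objects (>= 2) of the same model family,
#'   each retaining its fitted points.
#' @param method One of `"pooled"`, `"geometric_mean"`, `"shared_ftest"`.
#' @param alpha Significance level for the F-test flag.
#' @return An object of class `combined_ic50`: fields `method`, `logIC50`,
#'   `IC50_uM`, `ci95` (log scale), and for the F-test method
#'   `f_statistic`, `p_value`, `different_runs`.
#' @export
combine_ic50 <- function(runs, method = c("pooled", "geometric_mean",
                                          "shared_ftest"),
                         alpha = 0.05) {
  method <- match.arg(method)
  if (!is.list(runs) || length(runs) < 2L ||
      !all(vapply(runs, inherits, logical(1), "dr_fit"))) {
    stop_("`runs` must be a list of >= 2 dr_fit objects")
  }
  fams <- vapply(runs, function(f) f$model, character(1))
  if (length(unique(fams)) != 1L) {
    stop_("all runs must use the same model family (got: %s)",
          paste(unique(fams), collapse = ", "))
  }
  model <- fams[1]

  if (method == "geometric_mean") {
    l <- vapply(runs, function(f) ic50(f)[["logIC50"]], numeric(1))
    k <- length(l)
    m <- mean(l)
    se <- sd(l) / sqrt(k)
    ci <- m + c(-1, 1) * qt(0.975, k - 1) * se
    return(structure(list(method = method, logIC50 = m, IC50_uM = 10^m,
                          ci95 = ci, n_runs = k, per_run_logIC50 = l),
                     class = "combined_ic50"))
  }

  if (method == "pooled") {
    pts <- do.call(rbind, lapply(runs, function(f)
      f$data[, c("concentration_uM", "viability_pct")]))
    fit <- dr_fit(pts, model = model,
                  pin_bottom = runs[[1]]$pin_bottom)
    l <- ic50(fit)[["logIC50"]]
    lrow <- if (model == "4pl") "logIC50" else "logIC50_1"
    return(structure(list(method = method, logIC50 = l, IC50_uM = 10^l,
                          ci95 = unname(fit$ci95[lrow, ]),
                          n_runs = length(runs), fit = fit),
                     class = "combined_ic50"))
  }

  # shared_ftest
  shared <- fit_shared_logic50(runs, model)
  ss_sep <- sum(vapply(runs, function(f) f$ss_residual, numeric(1)))
  df_sep <- sum(vapply(runs, function(f) f$df, numeric(1)))
  ddf <- shared$df - df_sep
  fstat <- ((shared$ss - ss_sep) / ddf) / (ss_sep / df_sep)
  fstat <- max(fstat, 0)
  pval <- pf(fstat, ddf, df_sep, lower.tail = FALSE)
  structure(list(method = method, logIC50 = shared$logIC50,
                 IC50_uM = 10^shared$logIC50, ci95 = shared$ci95,
                 f_statistic = fstat, p_value = pval,
                 different_runs = pval < alpha, n_runs = length(runs),
                 df = c(ddf, df_sep)),
            class = "combined_ic50")
}

# Joint fit of all runs with per-run plateaus and slopes but one shared
# logIC50 (both site logIC50s shared for the biphasic family), using
# indexed parameter vectors in the nls formula.
fit_shared_logic50 <- function(runs, model) {
  pts <- do.call(rbind, lapply(seq_along(runs), function(i) {
    d <- runs[[i]]$data
    data.frame(X = d$X, y = d$viability_pct, run = i)
  }))
  k <- length(runs)
  run <- pts$run
  y <- pts$y; X <- pts$X
  get_par <- function(name) vapply(runs, function(f) f$params[[name]], numeric(1))

  if (model == "4pl") {
    start <- list(top = get_par("top"), bottom = get_par("bottom"),
                  hill = get_par("hill"),
                  l50 = mean(get_par("logIC50")))
    form <- y ~ bottom[run] + (top[run] - bottom[run]) /
      (1 + 10^((l50 - X) * hill[run]))
    p <- 3 * k + 1
  } else {
    start <- list(top = get_par("top"), bottom = get_par("bottom"),
                  frac = get_par("frac"), nH1 = get_par("nH1"),
                  nH2 = get_par("nH2"),
                  l501 = mean(get_par("logIC50_1")),
                  l502 = mean(get_par("logIC50_2")))
    form <- y ~ bottom[run] + (top[run] - bottom[run]) *
      (frac[run] / (1 + 10^((l501 - X) * nH1[run])) +
         (1 - frac[run]) / (1 + 10^((l502 - X) * nH2[run])))
    p <- 5 * k + 2
  }
  # base nls handles the indexed (per-run) parameter vectors; the port
  # algorithm is robust here because the separate fits supply the starts
  fit <- tryCatch(
    nls(form, data = list(y = y, X = X, run = run), start = start,
        algorithm = "port",
        control = nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) stop_("shared-logIC50 fit failed: %s",
                              conditionMessage(e))
  )
  df <- length(y) - p
  est <- coef(fit)
  lname <- if (model == "4pl") "l50" else "l501"
  se <- summary(fit)$coefficients[lname, "Std. Error"]
  ci <- est[[lname]] + c(-1, 1) * qt(0.975, df) * se
  list(logIC50 = est[[lname]], ss = sum(residuals(fit)^2), df = df,
       ci95 = ci, fit = fit)
}

#' @export
print.combined_ic50 <- function(x, ...) {
  lab <- c(pooled = "pooled points", geometric_mean = "geometric mean",
           shared_ftest = "shared logIC50 (extra-sum-of-squares F-test)")
  cat(sprintf("Combined IC50 (%s, %d runs)\n", lab[[x$method]], x$n_runs))
  cat(sprintf("  logIC50 = %.4f  [%.4f, %.4f]   IC50 = %.4g uM\n",
              x$logIC50, x$ci95[1], x$ci95[2], x$IC50_uM))
  if (x$method == "shared_ftest") {
    cat(sprintf("  F(%d, %d) = %.3f, p = %.4g -> runs %s\n",
                x$df[1], x$df[2], x$f_statistic, x$p_value,
                if (x$different_runs) "have statistically different IC50s"
                else "are consistent with a common IC50"))
  }
  invisible(x)
}
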