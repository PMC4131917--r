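#' Four-parameter logistic dose-response model
#'
#' `Y = bottom + (top - bottom) / (1 + 10^((logIC50 - X) * hill))` with
#' `X = log10(concentration)`. At `X = logIC50` the response is exactly
#' midway between the plateaus; with `hill > 0` the curve rises with `X`,
#' with `hill < 0` (the usual cytotoxicity orientation) it falls.
#'
#' @param X log10 concentration (vectorised).
#' @param top,bottom Plateaus, percent.
#' @param logIC50 log10 IC50.
#' @param hill Hill slope.
#' @return Response, percent.
#' @export
model_4pl <- function(X, top, bottom, logIC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logIC50 - X) * hill))
}

#' Biphasic (two-site) dose-response model
#'
#' A mixture of two logistic transitions sharing the overall plateaus:
#' `Y = bottom + (top - bottom) * [frac / (1 + 10^((logIC50_1 - X) nH1)) +
#' (1 - frac) / (1 + 10^((logIC50_2 - X) nH2))]`. `frac` is the weight of
#' the first (more sensitive) site; with `frac = 1` the model reduces
#' exactly to [model_4pl()]. Captures two cell sub-populations with
#' distinct drug sensitivities, e.g. the intermediate shoulder seen in
#' heterogeneous neurosphere cultures.
#'
#' @inheritParams model_4pl
#' @param frac Fraction of the first site, in `[0, 1]`.
#' @param logIC50_1,logIC50_2 Site log10 IC50s.
#' @param nH1,nH2 Site Hill slopes.
#' @return Response, percent.
#' @export
model_biphasic <- function(X, top, bottom, frac, logIC50_1, logIC50_2,
                           nH1, nH2) {
  span <- top - bottom
  bottom + span * (frac / (1 + 10^((logIC50_1 - X) * nH1)) +
                     (1 - frac) / (1 + 10^((logIC50_2 - X) * nH2)))
}

prepare_dr_points <- function(data) {
  need <- c("concentration_uM", "viability_pct")
  if (!all(need %in% names(data))) {
    stop_("data must have columns %s", paste(need, collapse = ", "))
  }
  data <- data[is.finite(data$viability_pct) &
                 is.finite(data$concentration_uM), , drop = FALSE]
  n_zero <- sum(data$concentration_uM == 0)
  # zero-concentration vehicle wells anchor normalisation; they have no
  # position in log space and never enter the fit
  data <- data[data$concentration_uM > 0, , drop = FALSE]
  data$X <- log10(data$concentration_uM)
  attr(data, "n_zero_dropped") <- n_zero
  data
}

#' Fit a dose-response curve
#'
#' Least-squares fit of normalised viability against log10 concentration,
#' with either the four-parameter logistic (`"4pl"`) or the biphasic
#' two-site model (`"biphasic"`). Replicate wells are fitted as individual
#' points (never averaged), preserving the residual degrees of freedom the
#' combination F-test relies on. Estimation is unweighted
#' Levenberg-Marquardt least squares; standard errors come from the
#' asymptotic residual covariance and 95% confidence intervals use t(df)
#' quantiles. Non-convergence is reported in the `converged` field, never
#' silently absorbed.
#'
#' Initialisation: plateaus from the mean response at the extreme
#' concentrations, logIC50 from the concentration whose mean response is
#' closest to the half-range (for the biphasic model the 25th/75th
#' percentile concentrations and `frac = 0.5`), slope magnitude 1 with the
#' sign read off the data. Biphasic site slopes are bounded to magnitude
#' `[0.1, 10]`, `frac` to `[0, 1]`, and the site order `logIC50_1 <
#' logIC50_2` is restored after fitting.
#'
#' @param data Data frame with columns `concentration_uM` and
#'   `viability_pct` (zero-concentration anchor wells are dropped from the
#'   fit). Extra columns such as `run_id` are retained.
#' @param model `"4pl"` or `"biphasic"`.
#' @param pin_bottom Optional fixed value for the bottom plateau (e.g. 0 on
#'   the normalised scale); default leaves it free.
#' @return An object of class `dr_fit`, supporting `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `vcov`, `plot` and `simulate` methods,
#'   plus [ic50()].
#' @examples
#' plate <- simulate_plate(plate_truth(seed = 42))
#' norm <- normalize_readings(plate, "cytotoxicity")
#' fit <- dr_fit(norm[norm$role == "sample", ], model = "4pl")
#' coef(fit)
#' @export
dr_fit <- function(data, model = c("4pl", "biphasic"), pin_bottom = NULL) {
  model <- match.arg(model)
  pts <- prepare_dr_points(data)
  xs <- sort(unique(pts$X))
  min_levels <- if (model == "4pl") 5L else 8L
  if (length(xs) < min_levels) {
    stop_("the %s model needs >= %d distinct positive concentrations (got %d)",
          model, min_levels, length(xs))
  }
  y <- pts$viability_pct
  X <- pts$X

  mean_by_x <- vapply(xs, function(v) mean(y[X == v]), numeric(1))
  y_lo <- mean_by_x[1L]; y_hi <- mean_by_x[length(xs)]
  top0 <- max(y_lo, y_hi); bot0 <- min(y_lo, y_hi)
  rising <- y_hi >= y_lo
  half <- (top0 + bot0) / 2
  x50 <- xs[which.min(abs(mean_by_x - half))]

  if (model == "4pl") {
    start <- c(top = top0, logIC50 = x50, hill = if (rising) 1 else -1)
    lower <- c(top = -Inf, logIC50 = -Inf, hill = -Inf)
    upper <- c(top = Inf, logIC50 = Inf, hill = Inf)
    if (is.null(pin_bottom)) {
      start <- c(bottom = bot0, start)
      lower <- c(bottom = -Inf, lower); upper <- c(bottom = Inf, upper)
    }
    eval_model <- function(p, x) {
      b <- if (is.null(pin_bottom)) p[["bottom"]] else pin_bottom
      model_4pl(x, p[["top"]], b, p[["logIC50"]], p[["hill"]])
    }
  } else {
    l10 <- unname(quantile(X, 0.25)); l20 <- unname(quantile(X, 0.75))
    s0 <- if (rising) 1 else -1
    start <- c(top = top0, frac = 0.5, logIC50_1 = l10, logIC50_2 = l20,
               nH1 = s0, nH2 = s0)
    lower <- c(top = -Inf, frac = 0, logIC50_1 = -Inf, logIC50_2 = -Inf,
               nH1 = if (rising) 0.1 else -10, nH2 = if (rising) 0.1 else -10)
    upper <- c(top = Inf, frac = 1, logIC50_1 = Inf, logIC50_2 = Inf,
               nH1 = if (rising) 10 else -0.1, nH2 = if (rising) 10 else -0.1)
    if (is.null(pin_bottom)) {
      start <- c(bottom = bot0, start)
      lower <- c(bottom = -Inf, lower); upper <- c(bottom = Inf, upper)
    }
    eval_model <- function(p, x) {
      b <- if (is.null(pin_bottom)) p[["bottom"]] else pin_bottom
      model_biphasic(x, p[["top"]], b, p[["frac"]], p[["logIC50_1"]],
                     p[["logIC50_2"]], p[["nH1"]], p[["nH2"]])
    }
  }

  n <- length(y)
  p <- length(start)
  df <- n - p
  if (df <= 0) stop_("not enough points: df = %d - %d <= 0", n, p)

  # Levenberg-Marquardt on the residual vector.  Tight ftol/ptol so exact
  # (noise-free) data converges all the way to the fixed point.
  resid_fn <- function(par) {
    names(par) <- names(start)
    y - eval_model(par, X)
  }
  run_lm <- function(st) minpack.lm::nls.lm(
    par = st, lower = lower[names(start)], upper = upper[names(start)],
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  starts <- list(start)
  if (model == "biphasic") {
    # the 7-parameter surface is multi-modal; a small deterministic grid of
    # starts over the mixture weight, site placement and first-site slope
    # guards against shoulder/site swaps
    s0 <- start[["nH1"]]
    for (fr in c(0.3, 0.7)) {
      st <- start; st[["frac"]] <- fr; starts <- c(starts, list(st))
    }
    st <- start
    st[["logIC50_1"]] <- min(X) + 0.3; st[["logIC50_2"]] <- max(X) - 0.3
    starts <- c(starts, list(st))
    for (sharp in c(2.5, 5)) {
      st <- start; st[["nH1"]] <- pmax(pmin(s0 * sharp, 10), -10)
      starts <- c(starts, list(st))
    }
  }
  fits <- lapply(starts, run_lm)
  out <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  est <- out$par
  names(est) <- names(start)
  converged <- out$info %in% 1:3     # 5 = iteration limit, 0 = bad input

  ss_res <- out$deviance
  sigma2 <- ss_res / df
  # asymptotic covariance from the Gauss-Newton approximation J'J
  covm <- tryCatch(sigma2 * solve(out$hessian), error = function(e) NULL)
  if (is.null(covm)) {
    covm <- matrix(NA_real_, p, p)
  }
  dimnames(covm) <- list(names(start), names(start))
  se <- setNames(sqrt(pmax(diag(covm), 0)), names(start))

  if (model == "biphasic" && est[["logIC50_1"]] > est[["logIC50_2"]]) {
    # identifiability: order the sites, relabelling slopes and weight
    nm <- names(est)
    perm <- nm
    perm[match(c("logIC50_1", "logIC50_2", "nH1", "nH2"), nm)] <-
      c("logIC50_2", "logIC50_1", "nH2", "nH1")
    est <- setNames(est[perm], nm)
    se <- setNames(se[perm], nm)
    covm <- covm[perm, perm, drop = FALSE]
    dimnames(covm) <- list(nm, nm)
    est[["frac"]] <- 1 - est[["frac"]]
  }
  tcrit <- qt(0.975, df)
  ci95 <- cbind(lower = est - tcrit * se, upper = est + tcrit * se)
  r2 <- 1 - ss_res / sum((y - mean(y))^2)

  structure(
    list(model = model, params = est, se = se, ci95 = ci95,
         ss_residual = ss_res, df = df, n = n, r2 = r2,
         converged = converged, pin_bottom = pin_bottom,
         cov = covm, data = pts,
         n_zero_dropped = attr(pts, "n_zero_dropped")),
    class = "dr_fit"
  )
}

#' Fit the four-parameter logistic model
#'
#' Convenience wrapper: `dr_fit(data, model = "4pl", ...)`.
#' @inheritParams dr_fit
#' @param ... Passed to [dr_fit()].
#' @export
fit_4pl <- function(data, ...) dr_fit(data, model = "4pl", ...)

#' Fit the biphasic two-site model
#'
#' Convenience wrapper: `dr_fit(data, model = "biphasic", ...)`.
#' @inheritParams dr_fit
#' @param ... Passed to [dr_fit()].
#' @export
fit_biphasic <- function(data, ...) dr_fit(data, model = "biphasic", ...)

dr_param_vector <- function(object) {
  p <- as.list(object$params)
  if (!is.null(object$pin_bottom)) p$bottom <- object$pin_bottom
  p
}

dr_curve <- function(object, X) {
  p <- dr_param_vector(object)
  if (object$model == "4pl") {
    model_4pl(X, p$top, p$bottom, p$logIC50, p$hill)
  } else {
    model_biphasic(X, p$top, p$bottom, p$frac, p$logIC50_1, p$logIC50_2,
                   p$nH1, p$nH2)
  }
}

#' Fitted logIC50 (and IC50 in uM) of a dose-response fit
#'
#' For the biphasic model the first (more sensitive) site is reported by
#' default.
#' @param object A `dr_fit`.
#' @param site 1 or 2 (biphasic only).
#' @return Named vector `c(logIC50, IC50_uM)`.
#' @export
ic50 <- function(object, site = 1L) {
  stopifnot(inherits(object, "dr_fit"))
  l <- if (object$model == "4pl") object$params[["logIC50"]] else
    object$params[[paste0("logIC50_", site)]]
  c(logIC50 = l, IC50_uM = 10^l)
}

#' @export
coef.dr_fit <- function(object, ...) object$params

#' @export
vcov.dr_fit <- function(object, ...) object$cov

#' @export
residuals.dr_fit <- function(object, ...) {
  object$data$viability_pct - dr_curve(object, object$data$X)
}

#' Predict viability from a fitted dose-response curve
#'
#' @param object A `dr_fit`.
#' @param newdata Data frame with column `concentration_uM` (or `X`); when
#'   omitted, fitted values at the data points are returned.
#' @param ... Unused.
#' @return Predicted viability, percent.
#' @export
#' @method predict dr_fit
predict.dr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(dr_curve(object, object$data$X))
  X <- if ("X" %in% names(newdata)) newdata$X else {
    if (any(newdata$concentration_uM <= 0)) {
      stop_("predictions need positive concentrations")
    }
    log10(newdata$concentration_uM)
  }
  dr_curve(object, X)
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s), %d points, df = %d%s\n",
              if (x$model == "4pl") "4-parameter logistic" else
                "biphasic two-site", x$n, x$df,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(round(x$params, 4))
  invisible(x)
}

#' @export
summary.dr_fit <- function(object, ...) {
  tab <- cbind(estimate = object$params, se = object$se, object$ci95)
  structure(list(model = object$model, coefficients = tab,
                 ss_residual = object$ss_residual, df = object$df,
                 r2 = object$r2, converged = object$converged,
                 n = object$n, ic50 = ic50(object)),
            class = "summary.dr_fit")
}

#' @export
print.summary.dr_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: %s model\n",
              if (x$model == "4pl") "four-parameter logistic" else
                "biphasic two-site"))
  cat(sprintf("  n = %d, df = %d, SS = %.4g, R2 = %.4f, converged: %s\n",
              x$n, x$df, x$ss_residual, x$r2, x$converged))
  printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("  IC50 = %.4g uM (logIC50 = %.4f)\n",
              x$ic50[["IC50_uM"]], x$ic50[["logIC50"]]))
  invisible(x)
}

#' @export
#' @method plot dr_fit
plot.dr_fit <- function(x, ...) {
  X <- x$data$X; y <- x$data$viability_pct
  plot(X, y, xlab = expression(log[10] ~ "concentration (uM)"),
       ylab = "viability (%)", pch = 16, col = "grey40", ...)
  xx <- seq(min(X) - 0.3, max(X) + 0.3, length.out = 200)
  lines(xx, dr_curve(x, xx), col = "steelblue", lwd = 2)
  l50 <- ic50(x)[["logIC50"]]
  abline(v = l50, lty = 3, col = "firebrick")
  invisible(x)
}

#' @export
#' @method simulate dr_fit
#' @importFrom stats simulate rnorm
simulate.dr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sdr <- sqrt(object$ss_residual / object$df)
  mu <- dr_curve(object, object$data$X)
  gen <- function() {
    d <- object$data
    d$viability_pct <- mu + rnorm(length(mu), 0, sdr)
    d
  }
  sims <- if (is.null(seed)) replicate(nsim, gen(), simplify = FALSE) else
    with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
  if (nsim == 1) sims[[1]] else sims
}

#' @importFrom graphics abline plot
#' @importFrom stats printCoefmat
NULL
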