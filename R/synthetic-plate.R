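#' Ground truth for a simulated cytotoxicity plate
#'
#' Declares the dose-response truth and noise model from which
#' [simulate_plate()] draws one 96-well plate. Defaults follow the standard
#' screen design: 9 etoposide-style concentrations spanning 0.03-300 uM in
#' half-log steps, 6 replicate spheroids per condition, and multiplicative
#' well noise with a stated CV (all plate variability is expressed as CV).
#'
#' @param model `"monophasic"` (4-parameter logistic) or `"biphasic"`
#'   (two-site logistic mixture).
#' @param top,bottom Upper/lower viability plateaus, percent; `bottom < top`.
#' @param logIC50 log10 IC50 in uM (monophasic).
#' @param hill Hill slope (monophasic); negative for falling viability.
#' @param logIC50_1,logIC50_2,frac,nH1,nH2 Biphasic parameters: the two
#'   site log10 IC50s (`logIC50_1 < logIC50_2`), the fraction of the
#'   sensitive population in `[0, 1]`, and the two slopes.
#' @param cv_percent Well-to-well CV of the raw readings, percent, per
#'   assay.
#' @param replicates Replicate wells per concentration (>= 2).
#' @param concentrations Dose levels in uM (>= 4).
#' @param assay Assay label carried into the readings.
#' @param seed Integer seed; identical truths give bit-identical plates.
#' @return An object of class `plate_truth`.
#' @export
plate_truth <- function(model = c("monophasic", "biphasic"),
                        top = 100, bottom = 0, logIC50 = 0.5, hill = -1,
                        logIC50_1 = -0.5, logIC50_2 = 1.5, frac = 0.5,
                        nH1 = -2.5, nH2 = -1,
                        cv_percent = 10, replicates = 6,
                        concentrations = c(0.03, 0.1, 0.3, 1, 3, 10, 30,
                                           100, 300),
                        assay = "volume", seed = 1L) {
  model <- match.arg(model)
  if (bottom >= top) stop_("bottom must be below top")
  if (cv_percent < 0) stop_("cv_percent must be >= 0")
  if (replicates < 2) stop_("need replicates >= 2")
  if (length(concentrations) < 4) stop_("need >= 4 concentrations")
  if (any(concentrations <= 0)) stop_("concentrations must be positive")
  if (model == "biphasic") {
    if (frac < 0 || frac > 1) stop_("frac must be in [0, 1]")
    if (logIC50_1 >= logIC50_2) stop_("need logIC50_1 < logIC50_2")
  }
  structure(
    list(model = model, top = top, bottom = bottom, logIC50 = logIC50,
         hill = hill, logIC50_1 = logIC50_1, logIC50_2 = logIC50_2,
         frac = frac, nH1 = nH1, nH2 = nH2, cv_percent = cv_percent,
         replicates = as.integer(replicates),
         concentrations = sort(as.numeric(concentrations)),
         assay = assay, seed = as.integer(seed)),
    class = "plate_truth"
  )
}

#' @export
print.plate_truth <- function(x, ...) {
  cat(sprintf("<plate_truth> %s, %d conc x %d reps, CV %.1f%%, seed %d\n",
              x$model, length(x$concentrations), x$replicates,
              x$cv_percent, x$seed))
  invisible(x)
}

#' True mean viability of a plate truth at given concentrations
#'
#' @param truth A [plate_truth].
#' @param conc_uM Concentrations in uM.
#' @return Percent viability on the truth curve.
#' @export
truth_viability <- function(truth, conc_uM) {
  stopifnot(inherits(truth, "plate_truth"))
  X <- log10(conc_uM)
  if (truth$model == "monophasic") {
    model_4pl(X, top = truth$top, bottom = truth$bottom,
              logIC50 = truth$logIC50, hill = truth$hill)
  } else {
    model_biphasic(X, top = truth$top, bottom = truth$bottom,
                   frac = truth$frac, logIC50_1 = truth$logIC50_1,
                   logIC50_2 = truth$logIC50_2, nH1 = truth$nH1,
                   nH2 = truth$nH2)
  }
}

# raw plate-reader units corresponding to 0% and 100% viability; readings
# are an affine image of viability so normalisation recovers percent exactly
.RAW0 <- 200
.RAW100 <- 2000
.RAW_MEDIA <- 180

#' Simulate raw readings for one cytotoxicity plate
#'
#' Lays out a 96-well plate in the standard screen design -- 9
#' concentrations across columns 1-9, replicates down rows A-F, negative
#' (vehicle) controls in column 10, positive (killed) controls in column
#' 11, and a media-only row H -- and draws each raw reading as the truth
#' curve's mean response in reader units perturbed by multiplicative
#' Gaussian noise with the stated CV. With `cv_percent = 0` the normalised
#' readings sit exactly on the truth curve.
#'
#' @param truth A [plate_truth].
#' @param run_id Run label carried into the readings.
#' @return A data frame of one row per well with columns `run_id`, `well`,
#'   `role`, `condition`, `concentration_uM`, `assay`, `reading`, carrying
#'   `truth` as attribute `"truth"`.
#' @export
simulate_plate <- function(truth, run_id = "run1") {
  stopifnot(inherits(truth, "plate_truth"))
  conc <- truth$concentrations
  reps <- truth$replicates
  if (length(conc) > 9L) stop_("plate layout holds at most 9 concentrations")
  if (reps > 6L) stop_("plate layout holds at most 6 replicates")

  rows <- LETTERS[1:6]
  wells <- character(); roles <- character(); conds <- character()
  cum <- numeric(); mu <- numeric()
  viab <- truth_viability(truth, conc)
  for (j in seq_along(conc)) {
    for (i in seq_len(reps)) {
      wells <- c(wells, paste0(rows[i], j))
      roles <- c(roles, "sample")
      conds <- c(conds, sprintf("conc_%g", conc[j]))
      cum <- c(cum, conc[j])
      mu <- c(mu, .RAW0 + (.RAW100 - .RAW0) * viab[j] / 100)
    }
  }
  for (i in seq_len(reps)) {
    wells <- c(wells, paste0(rows[i], 10)); roles <- c(roles, "negative_control")
    conds <- c(conds, "vehicle"); cum <- c(cum, NA_real_)
    mu <- c(mu, .RAW100)
    wells <- c(wells, paste0(rows[i], 11)); roles <- c(roles, "positive_control")
    conds <- c(conds, "killed"); cum <- c(cum, NA_real_)
    mu <- c(mu, .RAW0)
  }
  for (j in 1:12) {
    wells <- c(wells, paste0("H", j)); roles <- c(roles, "media_only")
    conds <- c(conds, "media"); cum <- c(cum, NA_real_)
    mu <- c(mu, .RAW_MEDIA)
  }

  reading <- with_seed(truth$seed, {
    mu * (1 + rnorm(length(mu), 0, truth$cv_percent / 100))
  })
  out <- data.frame(run_id = run_id, well = wells, role = roles,
                    condition = conds, concentration_uM = cum,
                    assay = truth$assay, reading = reading,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}
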