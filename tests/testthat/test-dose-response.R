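sample_points <- function(truth, seed_run = NULL, run_id = "run1") {
  if (!is.null(seed_run)) truth$seed <- seed_run
  pl <- normalize_readings(simulate_plate(truth, run_id = run_id),
                           "cytotoxicity")
  pl[pl$role == "sample", ]
}

test_that("the 4PL curve honours its midpoint and asymptotes", {
  expect_equal(model_4pl(0.5, 100, 0, 0.5, -1.3), 50)
  expect_equal(model_4pl(2, 80, 20, 2, 1), 50)
  expect_equal(model_4pl(1, 100, 0, 0, 1), 100 / (1 + 10^-1))
  expect_equal(model_4pl(1, 100, 0, 0, 1), 90.909, tolerance = 1e-4)
  # hill > 0 rises towards top, falls to bottom
  expect_equal(model_4pl(-50, 100, 0, 0, 1), 0, tolerance = 1e-12)
  expect_equal(model_4pl(50, 100, 0, 0, 1), 100)
  expect_equal(model_4pl(50, 100, 0, 0, -1), 0, tolerance = 1e-12)
})

test_that("the biphasic curve reduces to 4PL at frac 1 and shows the shoulder", {
  X <- seq(-2, 3, by = 0.1)
  expect_equal(model_biphasic(X, 100, 0, 1, 0.5, 2, -1.2, -1),
               model_4pl(X, 100, 0, 0.5, -1.2))
  # between well-separated sites the curve plateaus near half the span
  mid <- model_biphasic(0.5, 100, 0, 0.5, -1.5, 2.5, -3, -3)
  expect_equal(mid, 50, tolerance = 1)
  expect_equal(model_biphasic(50, 100, 0, 0.5, -1, 1, -1, -1), 0,
               tolerance = 1e-10)
})

test_that("noiseless 4PL data is recovered as an exact fixed point", {
  f <- fit_4pl(sample_points(plate_truth(logIC50 = 0.5, hill = -1,
                                         cv_percent = 0, seed = 1)))
  expect_true(f$converged)
  truth <- c(bottom = 0, top = 100, logIC50 = 0.5, hill = -1)
  expect_equal(coef(f)[names(truth)], truth, tolerance = 1e-6)
  expect_lt(f$ss_residual, 1e-10)
  # fitted midpoint identity
  expect_equal(predict(f, data.frame(X = coef(f)[["logIC50"]])),
               (coef(f)[["top"]] + coef(f)[["bottom"]]) / 2)
})

test_that("noiseless biphasic data is recovered exactly with ordered sites", {
  f <- fit_biphasic(sample_points(plate_truth(model = "biphasic",
                                              cv_percent = 0, seed = 2)))
  truth <- c(bottom = 0, top = 100, frac = 0.5, logIC50_1 = -0.5,
             logIC50_2 = 1.5, nH1 = -2.5, nH2 = -1)
  expect_equal(coef(f)[names(truth)], truth, tolerance = 1e-5)
  expect_lt(coef(f)[["logIC50_1"]], coef(f)[["logIC50_2"]])
})

test_that("fits refuse underdetermined designs", {
  d <- data.frame(concentration_uM = rep(10, 20),
                  viability_pct = rnorm(20, 50, 5))
  expect_error(fit_4pl(d), "distinct")
  d5 <- data.frame(concentration_uM = rep(c(0.1, 1, 10, 100, 1000), 2),
                   viability_pct = rnorm(10, 50, 5))
  expect_error(fit_biphasic(d5), "distinct")
})

test_that("zero-concentration anchor wells never enter the fit", {
  pts <- sample_points(plate_truth(cv_percent = 0, seed = 3))
  extra <- rbind(pts, within(pts[1:3, ], {
    concentration_uM <- 0; viability_pct <- 100
  }))
  f <- fit_4pl(extra)
  expect_equal(f$n, nrow(pts))
  expect_equal(f$n_zero_dropped, 3)
})

test_that("the bottom plateau can be pinned", {
  f <- fit_4pl(sample_points(plate_truth(cv_percent = 5, seed = 9)),
               pin_bottom = 0)
  expect_false("bottom" %in% names(coef(f)))
  expect_equal(predict(f, data.frame(X = 50)), 0, tolerance = 1e-8)
  expect_equal(f$df, f$n - 3)
})

test_that("fitted logIC50 is invariant to affine rescaling of the response", {
  pts <- sample_points(plate_truth(cv_percent = 10, seed = 17))
  f1 <- fit_4pl(pts)
  pts2 <- pts
  pts2$viability_pct <- 3.7 * pts$viability_pct + 42   # different 'units'
  f2 <- fit_4pl(pts2)
  expect_equal(coef(f2)[["logIC50"]], coef(f1)[["logIC50"]],
               tolerance = 1e-6)
  expect_equal(coef(f2)[["hill"]], coef(f1)[["hill"]], tolerance = 1e-6)
})

test_that("dr_fit objects expose the standard modelling interface", {
  pts <- sample_points(plate_truth(cv_percent = 8, seed = 23))
  f <- fit_4pl(pts)
  expect_s3_class(f, "dr_fit")
  expect_equal(dim(vcov(f)), c(4, 4))
  expect_identical(rownames(vcov(f)), names(coef(f)))
  expect_length(residuals(f), f$n)
  expect_equal(unname(ic50(f)[["IC50_uM"]]), 10^coef(f)[["logIC50"]])
  expect_true(all(f$ci95[, "lower"] <= coef(f) & coef(f) <= f$ci95[, "upper"]))
  expect_output(print(f), "4-parameter logistic")
  expect_output(print(summary(f)), "IC50")
  sim <- simulate(f, seed = 1)
  expect_equal(nrow(sim), f$n)
  expect_identical(simulate(f, seed = 5)$viability_pct,
                   simulate(f, seed = 5)$viability_pct)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})

test_that("identical replicate runs agree across all combination methods", {
  f <- fit_4pl(sample_points(plate_truth(cv_percent = 8, seed = 31)))
  runs <- list(f, f, f)
  g <- combine_ic50(runs, "geometric_mean")
  p <- combine_ic50(runs, "pooled")
  s <- combine_ic50(runs, "shared_ftest")
  expect_equal(g$logIC50, coef(f)[["logIC50"]])
  expect_equal(p$logIC50, coef(f)[["logIC50"]], tolerance = 1e-6)
  expect_equal(s$logIC50, coef(f)[["logIC50"]], tolerance = 1e-4)
  expect_lt(s$f_statistic, 1e-4)
  expect_gt(s$p_value, 0.999)
  expect_false(s$different_runs)
})

test_that("the geometric mean of 1 and 100 uM IC50s is 10 uM", {
  mk <- function(l, s) fit_4pl(sample_points(
    plate_truth(logIC50 = l, hill = -1, cv_percent = 0, seed = s)))
  g <- combine_ic50(list(mk(0, 1), mk(2, 2)), "geometric_mean")
  expect_equal(g$IC50_uM, 10, tolerance = 1e-6)
  # permutation invariance
  g2 <- combine_ic50(list(mk(2, 2), mk(0, 1)), "geometric_mean")
  expect_equal(g2$logIC50, g$logIC50)
})

test_that("pooled combination is invariant to point order", {
  f1 <- fit_4pl(sample_points(plate_truth(cv_percent = 10, seed = 41),
                              run_id = "a"))
  f2 <- fit_4pl(sample_points(plate_truth(cv_percent = 10, seed = 42),
                              run_id = "b"))
  p1 <- combine_ic50(list(f1, f2), "pooled")
  p2 <- combine_ic50(list(f2, f1), "pooled")
  # same optimum up to LM iteration ordering
  expect_equal(p1$logIC50, p2$logIC50, tolerance = 1e-6)
})

test_that("mixed model families cannot be combined", {
  f1 <- fit_4pl(sample_points(plate_truth(cv_percent = 5, seed = 51)))
  f2 <- fit_biphasic(sample_points(plate_truth(model = "biphasic",
                                               cv_percent = 5, seed = 52)))
  expect_error(combine_ic50(list(f1, f2), "pooled"), "family")
  expect_error(combine_ic50(list(f1), "pooled"), ">= 2")
})

test_that("biphasic does not spuriously beat 4PL on monophasic data", {
  set.seed(61)
  wins <- vapply(1:40, function(s) {
    pts <- sample_points(plate_truth(logIC50 = 0.5, hill = -1,
                                     cv_percent = 10, seed = 6000 + s))
    f4 <- fit_4pl(pts)
    fb <- fit_biphasic(pts)
    nested_ftest(f4, fb) < 0.05
  }, logical(1))
  expect_lte(mean(wins), 0.1)
})

test_that("geometric-mean CIs tend to be broader than pooled CIs on homogeneous runs", {
  widths <- vapply(1:15, function(s) {
    runs <- lapply(1:3, function(i) fit_4pl(sample_points(
      plate_truth(logIC50 = 0.5, hill = -1, cv_percent = 10,
                  seed = 7000 + 10 * s + i), run_id = paste0("r", i))))
    g <- combine_ic50(runs, "geometric_mean")
    p <- combine_ic50(runs, "pooled")
    c(diff(g$ci95), diff(p$ci95))
  }, numeric(2))
  # a statistical tendency over seeds, not a per-seed guarantee
  expect_gt(mean(widths[1, ]), mean(widths[2, ]))
})
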