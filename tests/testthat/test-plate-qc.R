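stats_of <- function(mean, sd, n = 6) summary_stats(list(mean = mean, sd = sd, n = n))

test_that("Z-factor closed forms and bounds", {
  expect_equal(z_factor(stats_of(100, 0), stats_of(0, 0)), 1)
  expect_equal(z_factor(stats_of(100, 5), stats_of(0, 5)), 0.7)
  # exactly the screening acceptance boundary
  expect_equal(z_factor(stats_of(100, 10), stats_of(0, 10)), 0.4)
  expect_error(z_factor(stats_of(50, 1), stats_of(50, 2)), "equal")
  # Z <= 1 with equality iff both SDs vanish
  set.seed(1)
  for (i in 1:50) {
    z <- z_factor(stats_of(runif(1, 50, 200), runif(1, 0, 30)),
                  stats_of(runif(1, -50, 40), runif(1, 0, 30)))
    expect_lte(z, 1)
  }
})

test_that("signal window closed forms", {
  expect_equal(signal_window(stats_of(100, 5), stats_of(0, 5)), 14)
  expect_equal(signal_window(stats_of(100, 10), stats_of(0, 10)), 4)
  # separation exactly eaten by 3 SDs of each group
  expect_equal(signal_window(stats_of(60, 5), stats_of(0, 15)), 0)
  expect_error(signal_window(stats_of(10, 0), stats_of(0, 1)), "positive")
})

test_that("CV closed forms and the 20% boundary", {
  expect_equal(cv_percent(stats_of(422, 21.1)), 5)
  expect_equal(cv_percent(stats_of(100, 0)), 0)
  expect_equal(cv_percent(stats_of(100, 20)), 20)  # fails the < 20% criterion
  expect_false(cv_percent(stats_of(100, 20)) < 20)
  expect_error(cv_percent(stats_of(0, 1)), "zero")
})

test_that("Z-factor and signal window are invariant under affine rescaling", {
  set.seed(9)
  s <- rnorm(8, 500, 40); c <- rnorm(8, 100, 25)
  for (i in 1:10) {
    gain <- runif(1, 0.1, 30); offset <- runif(1, -200, 200)
    expect_equal(z_factor(gain * s + offset, gain * c + offset),
                 z_factor(s, c))
    expect_equal(signal_window(gain * s + offset, gain * c + offset),
                 signal_window(s, c))
  }
})

test_that("growth increase reproduces the reported culture extremes", {
  expect_equal(growth_increase(5, 5), 0)
  expect_equal(growth_increase(1e6, 7e6), 600)   # strongest growth observed
  expect_equal(growth_increase(1e6, 2.7e6), 170)
  expect_error(growth_increase(0, 10), "positive")
})

test_that("residual drug fraction follows the exchange arithmetic", {
  expect_identical(residual_fraction(200, 150, 1), 0.25)
  expect_identical(residual_fraction(200, 150, 2), 0.0625)  # 1/16
  expect_identical(residual_fraction(200, 150, 0), 1)
  expect_error(residual_fraction(200, 250, 1), "exchanged_volume")
  expect_error(residual_fraction(200, 0, 1), "exchanged_volume")
  expect_error(residual_fraction(200, 150, 1.5), "integer")
})

test_that("anchor normalisation is linear, unclipped and idempotent", {
  expect_equal(normalize_to_anchors(c(500, 100, 300), 100, 500),
               c(100, 0, 50))
  expect_equal(normalize_to_anchors(700, 100, 500), 150)   # not clipped
  expect_error(normalize_to_anchors(1, 5, 5), "distinct")
  # idempotent once anchors are on the percent scale
  v <- c(0, 25, 50, 100, 120)
  expect_equal(normalize_to_anchors(v, 0, 100), v)
})

test_that("plate normalisation schemes anchor on the right wells", {
  pl <- simulate_plate(plate_truth(cv_percent = 5, seed = 4))
  cyto <- normalize_readings(pl, "cytotoxicity")
  expect_equal(mean(cyto$viability_pct[cyto$role == "negative_control"]), 100)
  expect_equal(mean(cyto$viability_pct[cyto$role == "positive_control"]), 0)
  val <- normalize_readings(pl, "validation")
  expect_equal(mean(val$viability_pct[val$role == "media_only"]), 0)
  expect_equal(max(val$viability_pct[val$role != "media_only"]), 100)
  expect_error(normalize_readings(pl[pl$role == "sample", ], "cytotoxicity"),
               "control")
})

test_that("the per-condition QC table applies the acceptance criteria", {
  pl <- simulate_plate(plate_truth(cv_percent = 5, seed = 13))
  qc <- plate_qc(pl, control = "positive_control")
  expect_s3_class(qc, "qc_report")
  expect_equal(nrow(qc), 9)
  expect_true(all(c("z_factor", "signal_window", "cv_percent",
                    "pass_z", "pass_sw", "pass_cv") %in% names(qc)))
  expect_identical(qc$pass_cv, qc$cv_percent < 20)
  expect_identical(qc$pass_z, !is.na(qc$z_factor) & qc$z_factor > 0.4)
  # low-dose conditions sit far from the killed control: tight assay passes
  top_cond <- qc[qc$condition == "conc_0.03", ]
  expect_true(top_cond$pass_z && top_cond$pass_sw && top_cond$pass_cv)
})
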