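test_that("equivalent-sphere closed forms hold", {
  eq <- equivalent_volume(pi)
  expect_equal(eq$radius, 1)
  expect_equal(eq$volume, 4 * pi / 3)
  # a 400-um-diameter spheroid, the working size of the screen
  eq2 <- equivalent_volume(pi * 200^2)
  expect_equal(eq2$radius, 200)
  expect_equal(eq2$volume, (4 / 3) * pi * 200^3)
  expect_equal(eq2$volume, 3.3510322e7, tolerance = 1e-7)
  expect_error(equivalent_volume(0), "positive")
  expect_error(equivalent_volume(-3), "positive")
})

test_that("volume scales as area^(3/2)", {
  s <- runif(5, 10, 1e5)
  expect_equal(equivalent_volume(2 * s)$volume,
               equivalent_volume(s)$volume * 2^1.5)
})

test_that("a noiseless disk is measured to within the macro's tolerance", {
  tr <- image_truth(c(100, 100), noise_sd = 0, seed = 1)
  m <- segment_spheroid(generate_spheroid_image(tr))
  expect_false(m$empty)
  expect_lt(abs(m$area_um2 - pi * 1e4) / (pi * 1e4), 0.02)
  expect_equal(m$feret_max_um, 200, tolerance = 0.02)
  expect_equal(m$feret_min_um, 200, tolerance = 0.02)
  # internal consistency: V and r derive exactly from S
  expect_equal(m$radius_um, sqrt(m$area_um2 / pi))
  expect_equal(m$volume_um3, (4 / 3) * pi * m$radius_um^3)
})

test_that("segmented area within 1% of truth for a noiseless disk", {
  tr <- image_truth(c(100, 100), noise_sd = 0, seed = 2)
  m <- segment_spheroid(generate_spheroid_image(tr))
  expect_lt(abs(m$area_um2 - true_area(tr)) / true_area(tr), 0.01)
})

test_that("debris is separated from the spheroid", {
  base <- image_truth(c(90, 70), orientation = 0.4, noise_sd = 0, seed = 6)
  with_debris <- image_truth(c(90, 70), orientation = 0.4, noise_sd = 0,
                             debris_count = 20, seed = 6)
  m0 <- segment_spheroid(generate_spheroid_image(base))
  m1 <- segment_spheroid(generate_spheroid_image(with_debris))
  expect_lt(abs(m1$area_um2 - true_area(with_debris)) /
              true_area(with_debris), 0.05)
  # non-touching debris changes the measurement by < 1%
  expect_lt(abs(m1$area_um2 - m0$area_um2) / m0$area_um2, 0.01)
})

test_that("scale calibration propagates as k, k^2, k^3", {
  mk <- function(k) {
    tr <- image_truth(c(80, 60), noise_sd = 4, debris_count = 3,
                      scale = k, seed = 8)
    segment_spheroid(generate_spheroid_image(tr))
  }
  m1 <- mk(1); m2 <- mk(2.5)
  expect_equal(m2$area_um2, m1$area_um2 * 2.5^2)
  expect_equal(m2$volume_um3, m1$volume_um3 * 2.5^3)
  expect_equal(m2$feret_max_um, m1$feret_max_um * 2.5)
  expect_equal(m2$feret_min_um, m1$feret_min_um * 2.5)
  expect_equal(m2$aspect_ratio, m1$aspect_ratio)
})

test_that("elongation beyond the 1.5 validity bound raises a flag", {
  tr <- image_truth(c(120, 70), noise_sd = 0, seed = 4)   # aspect 1.71
  m <- segment_spheroid(generate_spheroid_image(tr))
  expect_gt(m$aspect_ratio, 1.5)
  expect_true("aspect_gt_1.5" %in% m$flags)
  tr2 <- image_truth(c(80, 80), noise_sd = 0, seed = 4)
  expect_length(segment_spheroid(generate_spheroid_image(tr2))$flags, 0)
})

test_that("uncalibrated images are rejected", {
  expect_error(gray_image(matrix(1, 5, 5), scale = 0), "positive")
  expect_error(gray_image(matrix(1, 5, 5), scale = -2), "positive")
})

test_that("batch measurement emits one row per image in filename order", {
  folder <- withr::local_tempdir()
  out <- withr::local_tempdir()
  tr <- image_truth(c(60, 60), noise_sd = 3, seed = 5)
  img <- generate_spheroid_image(tr)
  for (i in 1:6) {
    write_gray_image(img, file.path(folder, sprintf("well_%02d.png", i)))
  }
  res <- batch_measure(folder, scale = 1.3, out_dir = out)
  expect_equal(nrow(res), 6)
  expect_equal(res$source_id, sprintf("well_%02d.png", 1:6))
  expect_equal(sd(res$area_um2), 0)            # identical inputs, CV 0
  expect_true(file.exists(file.path(out, "measurements.csv")))
  expect_true(all(file.exists(
    file.path(out, sprintf("well_%02d_outline.png", 1:6)))))
  # overlay copies are RGB with a blue outline
  ov <- png::readPNG(file.path(out, "well_01_outline.png"))
  expect_equal(dim(ov)[3], 3)
  expect_true(any(ov[, , 3] == 1 & ov[, , 1] == 0))
})

test_that("an unreadable file is flagged without aborting the batch", {
  folder <- withr::local_tempdir()
  tr <- image_truth(c(50, 50), noise_sd = 3, seed = 5)
  img <- generate_spheroid_image(tr)
  for (i in 1:9) {
    write_gray_image(img, file.path(folder, sprintf("img_%02d.png", i)))
  }
  writeLines("this is not a png", file.path(folder, "img_05.png"))
  res <- suppressMessages(batch_measure(folder, scale = 1))
  expect_equal(nrow(res), 9)
  flagged <- grepl("read_error", res$flags)
  expect_equal(sum(flagged), 1)
  expect_equal(res$source_id[flagged], "img_05.png")
  expect_error(batch_measure(withr::local_tempdir(), scale = 1), "no images")
})

test_that("measured diameter spread tracks the generated spread", {
  set.seed(33)
  diams <- 260 * (1 + rnorm(40, 0, 0.04))       # 4% diameter CV
  meas <- vapply(seq_along(diams), function(i) {
    tr <- image_truth(rep(diams[i] / 2, 2), noise_sd = 4, seed = 500 + i)
    segment_spheroid(generate_spheroid_image(tr))$diameter_um
  }, numeric(1))
  cv_true <- 100 * sd(diams) / mean(diams)
  cv_meas <- cv_percent(meas)
  expect_lt(abs(cv_meas - cv_true), 1.5)
})
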