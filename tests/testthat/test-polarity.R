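test_that("line profiles sample the image correctly", {
  img <- calibrated_image(matrix(7, 40, 60), 1)
  p <- extract_line_profile(img, c(5, 20), c(55, 20), width = 3)
  expect_true(all(abs(p$intensity - 7) < 1e-9))
  # a vertical step edge lands within a pixel of its true position
  m <- matrix(10, 40, 60); m[, 31:60] <- 110
  img2 <- calibrated_image(m, 1)
  p2 <- extract_line_profile(img2, c(2, 20), c(58, 20))
  mid <- (10 + 110) / 2
  crossing <- p2$position_um[min(which(p2$intensity > mid))] + 2
  expect_lt(abs(crossing - 30), 1.5)
  # synthetic tri-peak image scanned through its centre
  lp <- make_line_profile(c(0.3, 0.4, 0.3), noise_sd = 0)
  pk <- detect_peaks(lp$profile)
  expect_equal(nrow(pk), 3L)
  expect_lt(max(abs(pk$apex_position_um - lp$truth$peak_positions)), 1)
})

test_that("peak detection handles degenerate profiles", {
  x <- seq(0, 40, by = 0.1)
  g <- profile_of(x, 30 * exp(-(x - 20)^2 / 8))
  pk <- detect_peaks(g)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_position_um - 20), 0.2)
  expect_equal(nrow(detect_peaks(profile_of(x, x))), 0L)         # ramp
  expect_equal(nrow(detect_peaks(profile_of(x, rep(5, length(x))))), 0L)
})

test_that("areas match the Gaussian closed form and are symmetric", {
  x <- seq(0, 60, length.out = 600)  # >= 8 samples per sigma
  A <- 25; s <- 2
  y <- A * exp(-(x - 20)^2 / (2 * s^2)) + A * exp(-(x - 45)^2 / (2 * s^2))
  pk <- area_under_peaks(profile_of(x, y), detect_peaks(profile_of(x, y)))
  expect_equal(nrow(pk), 2L)
  closed <- A * s * sqrt(2 * pi)
  for (a in pk$area) expect_lt(abs(a - closed) / closed, 0.05)
  # two identical peaks: equal areas within 1%
  expect_lt(abs(pk$area[1] - pk$area[2]) / pk$area[1], 0.01)
  # uniform intensity scaling scales areas linearly (fractions unchanged)
  pk2 <- area_under_peaks(profile_of(x, 3 * y),
                          detect_peaks(profile_of(x, 3 * y)))
  expect_equal(pk2$area, 3 * pk$area, tolerance = 1e-9)
})

test_that("BMF fractions assign peaks by thirds and normalize to 100", {
  peaks <- data.frame(apex_position_um = c(4, 12, 20), area = c(1, 2, 1))
  b <- bmf_fractions(peaks, cluster_extent = c(0, 24))
  expect_equal(c(b$back, b$middle, b$front), c(25, 50, 25))
  expect_equal(b$back + b$middle + b$front, 100)
  # cortical-only profile: middle is zero
  b2 <- bmf_fractions(data.frame(apex_position_um = c(4, 20),
                                 area = c(3, 3)), c(0, 24))
  expect_equal(b2$middle, 0)
  # zero total area: undefined, not zero
  b3 <- bmf_fractions(data.frame(apex_position_um = 12, area = 0), c(0, 24))
  expect_true(is.na(b3$middle))
})

test_that("noise-free synthetic profiles are recovered within 2 points", {
  recover <- function(target) {
    lp <- make_line_profile(target, noise_sd = 0)
    pk <- area_under_peaks(lp$profile, detect_peaks(lp$profile))
    b <- bmf_fractions(pk, lp$truth$cluster_extent)
    c(b$back, b$middle, b$front)
  }
  for (target in list(c(0.25, 0.5, 0.25), c(0.425, 0.15, 0.425),
                      c(0.305, 0.39, 0.305), c(0.1, 0.6, 0.3))) {
    expect_lt(max(abs(recover(target) - 100 * target)), 2)
  }
})

test_that("middle fold shift is a plain ratio of middle fractions", {
  bmf <- function(b, m, f) structure(list(back = b, middle = m, front = f),
                                     class = "bmf_fractions")
  expect_equal(middle_fold_shift(bmf(31, 39, 30), bmf(42.5, 15, 42.5)), 2.6)
  expect_equal(middle_fold_shift(bmf(25, 50, 25), bmf(25, 50, 25)), 1)
  a <- bmf(30, 40, 30); b <- bmf(45, 10, 45)
  expect_equal(middle_fold_shift(a, b) * middle_fold_shift(b, a), 1)
  expect_error(middle_fold_shift(a, bmf(50, 0, 50)), "> 0")
})

test_that("raw integrated density sums intensities and is additive", {
  img <- calibrated_image(matrix(1, 10, 10), 1)
  m <- matrix(FALSE, 10, 10); m[1:5, 1:10] <- TRUE
  expect_equal(raw_integrated_density(img, m), 50)
  expect_equal(raw_integrated_density(img, matrix(FALSE, 10, 10)), 0)
  m2 <- !m
  expect_equal(raw_integrated_density(img, m) +
                 raw_integrated_density(img, m2),
               raw_integrated_density(img, matrix(TRUE, 10, 10)))
})

test_that("mosaic and junction ratios read out intensity folds", {
  ms <- make_mosaic(1.7, noise_sd = 0)
  mr <- mosaic_ratio(ms$image, ms$truth$test_mask, ms$truth$control_mask)
  expect_equal(mr$fold, 1.7, tolerance = 1e-12)
  ms1 <- make_mosaic(1, noise_sd = 0)
  mr1 <- mosaic_ratio(ms1$image, ms1$truth$test_mask, ms1$truth$control_mask)
  expect_equal(mr1$ratio, 1)
  # rid mode agrees with mean mode up to region sizes
  mrr <- mosaic_ratio(ms$image, ms$truth$test_mask, ms$truth$control_mask,
                      mode = "rid")
  expect_gt(mrr$fold, 1)
  # junction ratio: inner twice outer, invariant to global scaling
  m <- matrix(10, 20, 20); m[8:12, 8:12] <- 20
  inner <- matrix(FALSE, 20, 20); inner[8:12, 8:12] <- TRUE
  outer_m <- matrix(FALSE, 20, 20); outer_m[1:3, ] <- TRUE
  img <- calibrated_image(m, 1)
  expect_equal(junction_ratio(img, inner, outer_m), 2)
  img5 <- calibrated_image(5 * m, 1)
  expect_equal(junction_ratio(img5, inner, outer_m), 2)
})

test_that("mosaic fold is recovered within 5% at SNR 10 across seeds", {
  folds <- vapply(1:20, function(s) {
    ms <- make_mosaic(1.6, seed = s, noise_sd = 15)  # SNR = 150/15 = 10
    mosaic_ratio(ms$image, ms$truth$test_mask, ms$truth$control_mask)$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1.6) / 1.6, 0.05)
})
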