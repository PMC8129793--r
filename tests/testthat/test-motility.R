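test_that("centroid tracking converts pixel motion to physical units", {
  px <- 0.62
  m0 <- disk_mask(40, 60, 20, 15, 8)
  # static mask: constant track
  tr <- track_centroid(list(m0, m0, m0), px, 3)
  expect_equal(diff(tr$x_um), c(0, 0))
  # translation by 2 px/frame at 0.62 um/px: 1.24 um/frame
  masks <- lapply(0:3, function(k) disk_mask(40, 60, 20, 15 + 2 * k, 8))
  tr2 <- track_centroid(masks, px, 3)
  expect_equal(diff(tr2$x_um), rep(1.24, 3), tolerance = 1e-9)
})

test_that("forward speed is a mean of consecutive x increments", {
  tr <- data.frame(x_um = c(0, 1.35, 2.70))
  expect_equal(forward_speed(tr, frame_interval = 3), 0.45)
  expect_equal(forward_speed(data.frame(x_um = rep(7, 5)),
                             frame_interval = 3), 0)
  # translation invariance and inverse scaling with the frame interval
  expect_equal(forward_speed(data.frame(x_um = c(0, 1.35, 2.7) + 100),
                             frame_interval = 3), 0.45)
  expect_equal(forward_speed(tr, frame_interval = 1.5), 0.9)
})

test_that("percent reduction and migration index follow their definitions", {
  expect_equal(percent_reduction(0.45, 0.09), 80)
  expect_equal(percent_reduction(0.3, 0.3), 0)
  expect_equal(percent_reduction(0.3, 0), 100)
  expect_error(percent_reduction(0, 0.1), "> 0")
  expect_equal(migration_index(80, 20, 80), 100)
  expect_equal(migration_index(20, 20, 80), 0)
  expect_equal(migration_index(50, 20, 80), 50)
  expect_equal(migration_index(95, 20, 80), 100)  # clamped
  expect_equal(migration_index(5, 20, 80), 0)     # clamped
  expect_error(migration_index(50, 80, 20), "greater")
})

test_that("circularity separates disks from bars and ignores translation", {
  d <- disk_mask(100, 100, 50, 50, 30)
  expect_gte(roundness(d), 0.9)
  bar <- matrix(FALSE, 20, 20)
  bar[10, 5:14] <- TRUE  # 10 x 1 bar: 4*pi*A/P^2 = 4*pi*10/22^2 ~ 0.26
  expect_lt(roundness(bar), 0.5)
  d2 <- disk_mask(100, 100, 35, 60, 30)
  expect_equal(roundness(d), roundness(d2))
})

test_that("rearrangement detection responds to order changes only", {
  ring <- function(angles_deg, radii, centre = c(0, 0)) {
    th <- angles_deg * pi / 180
    data.frame(x_um = centre[1] + radii * cos(th),
               y_um = centre[2] - radii * sin(th))
  }
  a <- ring(c(10, 50, 180, 270), c(2, 6, 4, 4))
  expect_false(detect_rearrangement(a, a))
  # rigid translation of every nucleus preserves the circular order
  b <- a; b$x_um <- b$x_um + 3; b$y_um <- b$y_um + 1
  expect_false(detect_rearrangement(a, b))
  # two nuclei exchange angular rank (radii distinct, so identity tracking
  # survives): rearrangement
  cset <- ring(c(50, 10, 180, 270), c(2, 6, 4, 4))
  expect_true(detect_rearrangement(a, cset))
  # unequal counts: compared on the matched subset, with a message
  expect_message(detect_rearrangement(a, ring(c(12, 52, 182), c(2, 6, 4))),
                 "counts differ")
})

test_that("tumbling index applies the two-consecutive-frames rule", {
  # every first-half frame qualifies: 100%
  expect_equal(tumbling_index(rep(TRUE, 10), rep(TRUE, 10),
                              first_half = 1:5), 100)
  expect_equal(tumbling_index(rep(FALSE, 10), rep(TRUE, 10)), 0)
  # a single isolated qualifying frame does not count
  r <- rep(FALSE, 10); r[4] <- TRUE
  expect_equal(tumbling_index(r, r), 0)
  # two consecutive qualifying frames do
  r2 <- rep(FALSE, 10); r2[4:5] <- TRUE
  expect_equal(tumbling_index(r2, r2), 100 * 2 / 5)
  # monotone: extending a qualifying run never lowers the index
  vals <- vapply(2:5, function(k) {
    q <- rep(FALSE, 10); q[2:k] <- TRUE
    tumbling_index(q, q)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("movie analysis recovers the generator's track and speed", {
  sim <- make_timelapse(
    cluster_spec(), protrusion_spec(),
    motion_spec(forward_speed = 0.45, n_frames = 12, jitter_sd = 0),
    seed = 6)
  res <- suppressMessages(analyze_movie(sim$stack))
  # track within 0.5 um RMS of the truth-mask centroid, computed directly
  truth_cen <- t(vapply(sim$truth$full_masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    c((mean(idx[, 2]) - 0.5) * 0.62, (mean(idx[, 1]) - 0.5) * 0.62)
  }, numeric(2)))
  rms <- sqrt(mean((res$track$x_um - truth_cen[, 1])^2 +
                   (res$track$y_um - truth_cen[, 2])^2))
  expect_lt(rms, 0.5)
  expect_lt(abs(res$forward_speed_um_min - 0.45) / 0.45, 0.05)
  # a non-tumbling control shows no tumbling
  expect_equal(res$tumbling_index_pct, 0)
})
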