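test_that("explicit protrusion angles give deterministic, labelled truth", {
  cl <- small_cluster(noise_sd = 4)
  pr <- protrusion_spec(explicit_angles_deg = 0)
  fx1 <- make_fixed_cluster_image(cl, pr, seed = 1)
  fx2 <- make_fixed_cluster_image(cl, pr, seed = 2)
  expect_equal(nrow(fx1$truth$extensions), 1L)
  expect_equal(fx1$truth$extensions$sector, "front")
  # truth identical across seeds when angles are explicit...
  expect_identical(fx1$truth$extensions, fx2$truth$extensions)
  expect_identical(fx1$truth$full_mask, fx2$truth$full_mask)
  # ...but the noise fields differ
  expect_false(identical(fx1$image$pixels, fx2$image$pixels))
  # and the same seed is bit-identical
  fx1b <- make_fixed_cluster_image(cl, pr, seed = 1)
  expect_identical(fx1$image$pixels, fx1b$image$pixels)
})

test_that("truth masks partition the cluster: extensions disjoint from body", {
  fx <- make_fixed_cluster_image(
    small_cluster(noise_sd = 0),
    protrusion_spec(explicit_angles_deg = c(0, 90, 200)), seed = 1)
  tr <- fx$truth
  for (m in tr$ext_masks) expect_false(any(m & tr$body_mask))
  un <- Reduce(`|`, tr$ext_masks, tr$body_mask)
  expect_identical(un, tr$full_mask)
  if (length(tr$ext_masks) > 1) {
    for (i in seq_along(tr$ext_masks)[-1])
      for (j in seq_len(i - 1))
        expect_false(any(tr$ext_masks[[i]] & tr$ext_masks[[j]]))
  }
})

test_that("sampled sector fractions converge to the sector weights", {
  w <- c(front = 0.5, side = 0.25, back = 0.25)
  n <- 400L
  draws <- sample_protrusions(protrusion_spec(sector_weights = w), n,
                              seed = 11, min_separation_deg = 0)
  for (s in names(w)) {
    got <- sum(draws$sector == s) / n
    tol <- 3 * sqrt(w[[s]] * (1 - w[[s]]) / n)
    expect_lt(abs(got - w[[s]]), tol)
  }
  # sampled angles always classify into their recorded sector
  expect_identical(classify_sector(draws$angle_deg), draws$sector)
})

test_that("time-lapse truth track advances by speed x interval", {
  cl <- small_cluster()
  pr <- protrusion_spec(length_um = c(4, 6))
  mo <- motion_spec(forward_speed = 0.45, frame_interval = 3,
                    n_frames = 10, jitter_sd = 0)
  sim <- make_timelapse(cl, pr, mo, seed = 3)
  expect_equal(diff(sim$truth$track$x_um), rep(1.35, 9), tolerance = 1e-12)
  tr <- sim$truth$track
  attr(tr, "frame_interval") <- 3
  expect_equal(forward_speed(tr), 0.45, tolerance = 1e-12)
  # zero speed: constant track
  sim0 <- make_timelapse(cl, pr,
                         motion_spec(forward_speed = 0, n_frames = 5,
                                     jitter_sd = 0), seed = 3)
  expect_equal(diff(sim0$truth$track$x_um), rep(0, 4))
})

test_that("max-tumbling preset flags every first-half frame", {
  mo <- motion_spec_max_tumbling(20)
  sim <- make_timelapse(small_cluster(), protrusion_spec(), mo, seed = 1)
  expect_true(all(sim$truth$tumbling[1:10]))
  expect_false(any(sim$truth$tumbling[11:20]))
  # rendered tumbling frames carry no protrusions
  expect_false(any(sim$truth$extensions$frame %in% 1:10))
  # rearrangement applied at every within-episode transition
  expect_true(all(sim$truth$rearranged[2:10]))
})

test_that("generator rejects geometry that leaves the image", {
  cl <- small_cluster()
  expect_error(
    make_fixed_cluster_image(
      cl, protrusion_spec(explicit_angles_deg = 180, length_um = c(40, 40)),
      seed = 1),
    "exceeds the image extent")
  expect_error(
    make_timelapse(cl, protrusion_spec(),
                   motion_spec(forward_speed = 3, n_frames = 20,
                               jitter_sd = 0), seed = 1),
    "track leaves the image frame at frame [0-9]+")
})

test_that("line-profile generator honours target area ratios", {
  lp <- make_line_profile(c(0.25, 0.5, 0.25), noise_sd = 0)
  expect_equal(lp$truth$peak_areas / lp$truth$peak_areas[1], c(1, 2, 1))
  # zero middle target: no middle peak rendered
  lp2 <- make_line_profile(c(0.5, 0, 0.5), noise_sd = 0)
  expect_equal(lp2$truth$peak_areas[2], 0)
  mid <- lp2$truth$peak_positions[2]
  at_mid <- lp2$profile$intensity[which.min(abs(lp2$profile$position_um - mid))]
  expect_lt(at_mid, lp2$truth$baseline + 1)
  # determinism under a fixed seed
  a <- make_line_profile(c(0.3, 0.4, 0.3), noise_sd = 3, seed = 5)
  b <- make_line_profile(c(0.3, 0.4, 0.3), noise_sd = 3, seed = 5)
  expect_identical(a$profile, b$profile)
})

test_that("mosaic generator produces the requested fold exactly when clean", {
  ms <- make_mosaic(1.7, noise_sd = 0)
  mean_c <- mean(ms$image$pixels[ms$truth$control_mask])
  mean_t <- mean(ms$image$pixels[ms$truth$test_mask])
  expect_equal(mean_c / mean_t, 1.7, tolerance = 1e-12)
  ms1 <- make_mosaic(1, noise_sd = 0)
  expect_equal(mean(ms1$image$pixels[ms1$truth$control_mask]),
               mean(ms1$image$pixels[ms1$truth$test_mask]))
})

test_that("promoter fixture files round-trip through the readers", {
  dir <- withr::local_tempdir()
  fx <- make_promoter_fixture(25, 60, n_replicates = 2, seed = 4, dir = dir)
  genes <- read_gene_table(fx$files$genes)
  expect_equal(genes, fx$genes)
  bed <- read_bed(fx$files$beds[1])
  expect_equal(bed[c("chrom", "start", "end")], fx$peaks[[1]],
               ignore_attr = TRUE)
})
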