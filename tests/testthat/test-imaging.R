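test_that("max projection equals the per-pixel maximum over slices", {
  px <- 0.62
  s1 <- calibrated_image(matrix(1, 4, 4), px)
  s2 <- calibrated_image(matrix(5, 4, 4), px)
  out <- max_project(image_stack(list(s1, s2)))
  expect_equal(out$pixels, matrix(5, 4, 4))
  # single slice is the identity
  one <- max_project(image_stack(list(s1)))
  expect_equal(one$pixels, s1$pixels)
  # random 3-slice stack against an exhaustive loop
  set.seed(42)
  slices <- replicate(3, matrix(runif(30, 0, 10), 5, 6), simplify = FALSE)
  got <- max_project(image_stack(lapply(slices, calibrated_image,
                                        pixel_size = px)))$pixels
  want <- matrix(NA_real_, 5, 6)
  for (i in 1:5) for (j in 1:6)
    want[i, j] <- max(slices[[1]][i, j], slices[[2]][i, j], slices[[3]][i, j])
  expect_equal(got, want)
})

test_that("orientation is lossless and flags the result", {
  set.seed(1)
  img <- calibrated_image(matrix(runif(48), 6, 8), 0.5)
  left <- orient_anterior_left(img, "left")
  expect_identical(left$pixels, img$pixels)
  expect_true(left$oriented_anterior_left)
  # mirroring for anterior-right is an involution
  right <- orient_anterior_left(img, "right")
  back <- orient_anterior_left(right, "right")
  expect_identical(back$pixels, img$pixels)
  # 90-degree reorientation conserves every pixel
  top <- orient_anterior_left(img, "top")
  expect_equal(dim(top$pixels), c(8L, 6L))
  expect_equal(sort(as.vector(top$pixels)), sort(as.vector(img$pixels)))
  # the anterior (top) edge ends up at the left
  expect_equal(top$pixels[, 1], img$pixels[1, ])
})

test_that("background subtraction clamps at zero and records its estimate", {
  img <- calibrated_image(matrix(10, 5, 5), 1)
  out <- subtract_background(img, "constant", 10)
  expect_equal(out$pixels, matrix(0, 5, 5))
  expect_equal(attr(out, "background"), 10)
  # percentile estimate recovers the generator's background level
  cl <- small_cluster(intensity_bg = 100, intensity_fg = 250, noise_sd = 6)
  fx <- make_fixed_cluster_image(cl, protrusion_spec(explicit_angles_deg = 0),
                                 seed = 2)
  est <- attr(subtract_background(fx$image, "percentile", 5), "background")
  expect_lt(abs(est - 100), 3 * 6)
  # subtraction never yields negatives
  big <- subtract_background(fx$image, "constant", 1e5)
  expect_true(all(big$pixels >= 0))
})

test_that("cluster thresholding finds the cluster and is scale invariant", {
  # bimodal image: otsu separates the two levels
  m <- matrix(50, 10, 10)
  m[4:7, 4:7] <- 200
  img <- calibrated_image(m, 1)
  mask <- threshold_cluster(img, "otsu")
  expect_equal(unname(mask), m == 200, ignore_attr = TRUE)
  # absolute threshold above the maximum: no cluster
  expect_error(threshold_cluster(img, "absolute", value = 300),
               "no cluster found")
  # otsu on c * image gives the same mask
  img2 <- calibrated_image(3.7 * m, 1)
  expect_equal(threshold_cluster(img2, "otsu"), mask, ignore_attr = TRUE)
  # synthetic cluster at SNR 10: IoU with truth >= 0.9
  cl <- small_cluster(noise_sd = (200 - 20) / 10)
  fx <- make_fixed_cluster_image(
    cl, protrusion_spec(explicit_angles_deg = c(0, 120)), seed = 5)
  got <- threshold_cluster(fx$image)
  iou <- sum(got & fx$truth$full_mask) / sum(got | fx$truth$full_mask)
  expect_gte(iou, 0.9)
})

test_that("body/extension split partitions the mask and finds the lobes", {
  px <- 0.62
  # plain disk: no extensions
  d <- disk_mask(80, 80, 40, 40, 15)
  seg <- split_body_extensions(d, px)
  expect_length(seg$extensions, 0L)
  expect_identical(seg$body_mask, d)
  # disk plus one rectangular lobe: one extension, area within 15% of truth
  lobe <- matrix(FALSE, 80, 80)
  lobe[37:43, 40:70] <- TRUE   # 7 px wide bar through the disk, to the right
  full <- d | lobe
  truth_area <- sum(lobe & !d) * px^2
  seg1 <- split_body_extensions(full, px)
  expect_length(seg1$extensions, 1L)
  expect_lt(abs(seg1$summary$area_um2 - truth_area) / truth_area, 0.15)
  # partition: areas add up exactly
  expect_equal(sum(seg1$body_mask) +
                 sum(vapply(seg1$extensions, sum, numeric(1))),
               sum(full))
  # three lobes at 0, 90, 200 degrees from generator truth
  fx <- make_fixed_cluster_image(
    small_cluster(noise_sd = 0),
    protrusion_spec(explicit_angles_deg = c(0, 90, 200)), seed = 1)
  seg3 <- split_body_extensions(fx$truth$full_mask, 0.62)
  expect_length(seg3$extensions, 3L)
  # extension count is non-increasing as min_extension_area grows
  ns <- vapply(c(1, 5, 15, 40, 200), function(a) {
    length(split_body_extensions(fx$truth$full_mask, 0.62,
                                 min_extension_area = a)$extensions)
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  # opening that erases the whole mask is rejected with advice
  thin <- matrix(FALSE, 40, 40); thin[20, 5:35] <- TRUE
  expect_error(split_body_extensions(thin, 1, opening_radius = 5),
               "smaller")
})

test_that("calibrated TIFF round-trips single frames and stacks", {
  img <- calibrated_image(matrix(round(runif(100, 0, 60000)), 10, 10), 0.62)
  f <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_tiff(img, f)
  back <- read_calibrated_tiff(f, pixel_size = 0.62)
  expect_equal(back$pixels, img$pixels)
  stk <- image_stack(list(img, img), frame_interval = 3)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_tiff(stk, f2)
  back2 <- read_calibrated_tiff(f2, pixel_size = 0.62)
  expect_s3_class(back2, "image_stack")
  expect_equal(back2$frames[[2]]$pixels, img$pixels)
})
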