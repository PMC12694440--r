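test_that("the plausible-range gate invalidates sentinels and outliers only", {
  cfg <- depth_filter_config(min_depth_mm = 200, max_depth_mm = 2000)
  d <- matrix(c(0, 452, 2500, 200, 2000, 199), 2, 3)
  out <- filter_depth(d, cfg)
  expect_identical(as.vector(out), c(0, 452, 0, 200, 2000, 0))
})

test_that("median smoothing ignores invalid pixels and matches brute force", {
  cfg <- depth_filter_config(median_kernel = 3)
  const <- matrix(450, 6, 6)
  expect_identical(median_smooth(const, cfg), const)

  spike <- matrix(450, 7, 7); spike[4, 4] <- 2000
  sm <- median_smooth(spike, cfg)
  expect_equal(sm[4, 4], 450)
  expect_identical(sm, median_smooth_brute(spike, 3))

  allbad <- matrix(0, 5, 5)
  expect_identical(median_smooth(allbad, cfg), allbad)

  set.seed(8)
  for (i in 1:10) {
    d <- matrix(sample(c(0, 400:460), 64, replace = TRUE), 8, 8)
    sm <- median_smooth(d, cfg)
    expect_identical(sm == 0, d == 0)         # invalid pattern untouched
    expect_equal(sm, median_smooth_brute(d, 3))
  }
})

test_that("masked region averaging matches the per-pixel loop oracle", {
  cfg <- depth_filter_config(min_valid_pixels = 1)
  reg <- region_spec(0.2, 0.8, 0.25, 0.75)
  const <- matrix(450, 40, 40)
  full <- matrix(TRUE, 40, 40)
  expect_equal(region_mean_depth(const, full, reg, cfg), 45.0)

  split <- matrix(rep(c(400, 500), each = 20 * 40), 40, 40)
  expect_equal(region_mean_depth(split, full, reg, cfg), 45.0)

  set.seed(12)
  for (i in 1:8) {
    h <- sample(20:128, 1); w <- sample(20:128, 1)
    d <- matrix(sample(c(0, 300:700), h * w, replace = TRUE), h, w)
    m <- matrix(runif(h * w) < 0.6, h, w)
    oracle <- region_mean_brute(d, m, reg)
    if (oracle$n >= 1)
      expect_equal(region_mean_depth(d, m, reg, cfg), oracle$mean_cm,
                   tolerance = 1e-12)
  }
})

test_that("too few shoot pixels raise insufficient evidence; extract falls back", {
  cfg <- depth_filter_config(min_valid_pixels = 25)
  d <- matrix(450, 30, 30)
  sparse <- matrix(FALSE, 30, 30); sparse[15, 15] <- TRUE
  expect_error(region_mean_depth(d, sparse, region_spec(0.1, 0.9, 0.1, 0.9), cfg),
               class = "teaprof_insufficient_evidence")
  prof <- extract_l_values(list(depth = d), sparse, cfg = cfg)
  expect_true(prof$fallback_near && prof$fallback_far)
  expect_equal(prof$l_near, 45.0)  # whole-region valid mean
})

test_that("synthetic frames recover the true depth pair through the full chain", {
  g <- generate_canopy_frame(scene_params(illumination = "low", seed = 7))
  seg <- segment_shoots(g$frame$rgb)
  prof <- extract_l_values(g$frame, seg)
  expect_lte(abs(prof$l_near - g$truth$true_l_near), 0.5)
  expect_lte(abs(prof$l_far - g$truth$true_l_far), 0.5)
  expect_false(prof$fallback_near || prof$fallback_far)
  # arc geometry: the left (edge) region is deeper than the central one
  expect_gt(prof$l_far, prof$l_near)
})

test_that("narrowing the central region onto a tall central shoot lowers l_near", {
  h <- 80; w <- 112
  cx <- w / 2; cy <- h / 2
  bump <- outer(seq_len(h), seq_len(w), function(i, j)
    80 * exp(-((i - cy)^2 + (j - cx)^2) / (2 * 12^2)))
  d <- matrix(500, h, w) - bump   # tall shoot = closer = smaller depth
  full <- matrix(TRUE, h, w)
  cfg <- depth_filter_config(min_valid_pixels = 1)
  widths <- list(c(4, 10), c(5, 9), c(6, 8))
  l <- sapply(widths, function(cw)
    region_mean_depth(d, full, region_spec(cw[1] / 14, cw[2] / 14, 3 / 8, 5 / 8), cfg))
  expect_true(all(diff(l) < 0))
})

test_that("masking out deeper old leaves moves the mean toward the shoot surface", {
  g <- generate_canopy_frame(scene_params(
    illumination = "low", old_leaf_depth_offset = 6, depth_noise_sd = 0,
    hole_fraction = 0, seed = 15))
  cfg <- depth_filter_config()
  d <- median_smooth(filter_depth(g$frame$depth, cfg), cfg)
  reg <- near_region_default()
  masked <- region_mean_depth(d, g$truth$shoot_mask, reg, cfg)
  unmasked <- region_mean_depth(d, matrix(TRUE, nrow(d), ncol(d)), reg, cfg)
  expect_lt(masked, unmasked)
  expect_lt(abs(masked - g$truth$true_l_near), 0.1)
})

test_that("depth math is unit-consistent (scaling raster and gate scales l)", {
  set.seed(3)
  d <- matrix(sample(400:500, 900, replace = TRUE), 30, 30)
  m <- matrix(runif(900) < 0.7, 30, 30)
  reg <- region_spec(0.1, 0.9, 0.1, 0.9)
  cfg1 <- depth_filter_config(min_depth_mm = 200, max_depth_mm = 2000,
                              median_kernel = 1, min_valid_pixels = 1)
  cfg2 <- depth_filter_config(min_depth_mm = 400, max_depth_mm = 4000,
                              median_kernel = 1, min_valid_pixels = 1)
  l1 <- region_mean_depth(filter_depth(d, cfg1), m, reg, cfg1)
  l2 <- region_mean_depth(filter_depth(d * 2, cfg2), m, reg, cfg2)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
})

test_that("degenerate regions and misaligned rasters are rejected", {
  expect_error(region_spec(0.5, 0.4, 0.1, 0.9), class = "teaprof_parameter_error")
  expect_error(region_mean_depth(matrix(450, 10, 10), matrix(TRUE, 9, 9),
                                 region_spec(0.1, 0.9, 0.1, 0.9)),
               class = "teaprof_parameter_error")
})
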