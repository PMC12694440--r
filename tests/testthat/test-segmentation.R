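test_that("average gray equals the per-pixel luminance mean", {
  expect_equal(average_gray(uniform_rgb(100, 100, 100)), 100)
  half <- uniform_rgb(0, 0, 0, h = 4, w = 8)
  half[, 5:8, ] <- 200
  expect_equal(average_gray(half), 100)
  set.seed(31)
  img <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), dim = c(24, 24, 3))
  brute <- mean(sapply(seq_len(24 * 24), function(k) {
    i <- (k - 1) %% 24 + 1; j <- (k - 1) %/% 24 + 1
    0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] + 0.114 * img[i, j, 3]
  }))
  expect_lt(abs(average_gray(img) - brute), 0.5)
})

test_that("lighting classification follows the half-open AG bands", {
  cases <- list(
    list(124, "low_light"), list(166, "high_light"),
    list(90, "low_light"), list(140, "high_light"),
    list(220, "high_light"), list(89.9, "out_of_range"),
    list(220.5, "out_of_range"), list(10, "out_of_range"))
  for (c in cases)
    expect_identical(classify_lighting(c[[1]])$label, c[[2]])
})

test_that("super-green index matches hand evaluation and clamps", {
  expect_equal(supergreen(uniform_rgb(100, 100, 100))[1, 1], 50)
  expect_equal(supergreen(uniform_rgb(0, 255, 0))[1, 1], 255)
  expect_equal(supergreen(uniform_rgb(255, 0, 255))[1, 1], 0)
  # exact halving of R, no integer truncation: 2*10 - 5/2 - 0 = 17.5 -> 18
  expect_equal(supergreen(uniform_rgb(5, 10, 0))[1, 1], 18)
})

test_that("green-dominant pixels keep at least half their G value in the index", {
  set.seed(7)
  for (i in 1:200) {
    g <- sample(1:255, 1)
    r <- sample(0:g, 1); b <- sample(0:g, 1)
    expect_gte(supergreen(uniform_rgb(r, g, b, 1, 1))[1, 1], g / 2 - 0.5)
  }
})

test_that("CLAHE keeps constants constant, widens mode separation, stays 8-bit", {
  const <- uniform_rgb(80, 120, 60, 32, 32)
  out <- clahe_enhance(const)
  expect_equal(length(unique(as.vector(out[, , 2]))), 1L)
  expect_true(all(out >= 0 & out <= 255))

  set.seed(1)
  h <- 64; w <- 64
  stripe <- rep(rep(c(100, 118), each = 8), length.out = h)
  pop <- matrix(stripe, h, w)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- round(pmin(pmax(pop + matrix(rnorm(h * w, 0, 2), h, w), 0), 255))
  lum <- function(x) 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  enh <- clahe_enhance(img)
  a <- pop == 100
  sep_before <- mean(lum(img)[!a]) - mean(lum(img)[a])
  sep_after <- mean(lum(enh)[!a]) - mean(lum(enh)[a])
  expect_gt(sep_after, sep_before)
  expect_true(all(enh >= 0 & enh <= 255))

  expect_error(clahe_enhance(uniform_rgb(1, 1, 1, 4, 4)), "tile",
               class = "teaprof_parameter_error")
})

test_that("specular rule marks only pixels whose darkest channel saturates", {
  expect_true(specular_mask(uniform_rgb(255, 255, 255))[1, 1])
  expect_false(specular_mask(uniform_rgb(250, 250, 200))[1, 1])
  expect_true(specular_mask(uniform_rgb(230, 230, 230))[1, 1])
})

test_that("Otsu equals the exhaustive variance maximizer, with and without zeros", {
  bim <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t0 <- otsu_threshold(bim)
  expect_identical(t0, otsu_brute(bim))
  expect_true(t0 >= 10 && t0 < 200)

  # zero padding is invisible under exclude_zero
  padded <- cbind(bim, matrix(0, 10, 4))
  expect_identical(otsu_threshold(padded, exclude_zero = TRUE), t0)

  set.seed(42)
  for (i in 1:30) {
    g <- random_gray(16, 16, sample(0:255, sample(3:12, 1)))
    expect_identical(otsu_threshold(g), otsu_brute(g))
    if (length(unique(g[g != 0])) >= 2)
      expect_identical(otsu_threshold(g, TRUE), otsu_brute(g, TRUE))
  }

  expect_error(otsu_threshold(matrix(7, 4, 4)),
               class = "teaprof_degenerate_histogram")
  expect_error(otsu_threshold(matrix(c(0, 0, 0, 9), 2, 2), exclude_zero = TRUE),
               class = "teaprof_degenerate_histogram")
})

test_that("erosion follows set algebra with a square element", {
  cfg <- segmentation_config()
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_false(any(morphological_erode(lone, cfg)))

  rect <- matrix(FALSE, 20, 20); rect[5:14, 6:17] <- TRUE
  er <- morphological_erode(rect, cfg)
  expected <- matrix(FALSE, 20, 20); expected[6:13, 7:16] <- TRUE
  expect_identical(er, expected)
  expect_true(all(!er | rect))  # foreground shrinks only

  empty <- matrix(FALSE, 8, 8)
  expect_identical(morphological_erode(empty, cfg), empty)
})

test_that("low-light segmentation recovers the generator truth", {
  g <- generate_canopy_frame(scene_params(illumination = "low", seed = 7))
  seg <- segment_shoots(g$frame$rgb)
  expect_identical(seg$lighting$label, "low_light")
  sc <- detection_score(score_mask(seg, g$truth$shoot_mask))
  expect_gte(sc$precision, 0.90)
  expect_gte(sc$recall, 0.90)
  # deterministic: same frame, same mask
  expect_identical(seg$mask, segment_shoots(g$frame$rgb)$mask)
})

test_that("high-light segmentation excludes specular pixels and stays accurate", {
  g <- generate_canopy_frame(scene_params(illumination = "high",
                                          specular_fraction = 0.03, seed = 11))
  seg <- segment_shoots(g$frame$rgb)
  expect_identical(seg$lighting$label, "high_light")
  expect_equal(sum(seg$mask & g$truth$specular_mask), 0L)
  sc <- detection_score(score_mask(seg, g$truth$shoot_mask))
  expect_gte(sc$precision, 0.90)
  # specular-occluded shoots are forced background by design; recall over
  # observable (non-specular) shoot pixels
  observable <- g$truth$shoot_mask & !g$truth$specular_mask
  expect_gte(sum(seg$mask & observable) / sum(observable), 0.90)
})

test_that("a shootless canopy yields near-empty foreground", {
  g <- generate_canopy_frame(scene_params(shoot_density = 0,
                                          illumination = "low", seed = 3))
  seg <- segment_shoots(g$frame$rgb)
  expect_lte(seg$foreground_fraction, 0.01)
})

test_that("out-of-band AG raises a lighting error unless a class is forced", {
  dark <- uniform_rgb(20, 30, 20, 32, 32)
  expect_error(segment_shoots(dark), class = "teaprof_lighting_error")
  g <- generate_canopy_frame(scene_params(illumination = "low", seed = 4))
  seg_forced <- segment_shoots(g$frame$rgb, force_class = "high_light")
  expect_identical(seg_forced$lighting$label, "high_light")
})
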