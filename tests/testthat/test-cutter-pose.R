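rig <- rig_config(a_near = 55, a_far = 61, L = 10)

test_that("height adjustment reproduces the printed mount/weather cases", {
  expect_equal(compute_d(rig, 45.9412), -0.9412, tolerance = 1e-12)
  expect_equal(compute_d(rig, 35.1825), 9.8175, tolerance = 1e-12)
  expect_equal(compute_d(rig, 42.6136), 2.3864, tolerance = 1e-12)
  expect_equal(compute_d(rig, rig$a_near - rig$L), 0)
  expect_error(compute_d(rig, -1), class = "teaprof_parameter_error")
})

test_that("d is affine in l_near", {
  set.seed(5)
  l <- runif(20, 30, 60); delta <- runif(20, -5, 5)
  expect_equal(compute_d(rig, l + delta), compute_d(rig, l) - delta,
               tolerance = 1e-12)
})

test_that("rotation angle matches direct formula evaluation and is monotone", {
  expect_equal(compute_alpha(rig, rig$a_far - rig$L), 0)
  # independent hand evaluation of (L - (a_far - l_far)) * 180 / (r pi)
  hand <- (10 - (61 - 53.3801)) * 180 / (114 * pi)
  expect_equal(compute_alpha(rig, 53.3801), hand, tolerance = 1e-12)
  expect_equal(hand, 1.1962, tolerance = 1e-3)
  l <- seq(45, 60, by = 0.5)
  expect_true(all(diff(compute_alpha(rig, l)) > 0))
})

test_that("actuator displacement inverts the law-of-cosines linkage", {
  expect_equal(compute_delta_x(rig, 0), 0, tolerance = 1e-12)

  # forward round-trip at the worked example
  dx <- compute_delta_x(rig, 5, c_current = 80)
  expect_equal(alpha_from_delta_x(rig, dx, c_current = 80), 5, tolerance = 1e-9)

  # cross-check against numeric root finding on the forward equation
  root <- uniroot(function(z) alpha_from_delta_x(rig, z, c_current = 80) - 5,
                  interval = c(-5, 60), tol = 1e-12)$root
  expect_equal(dx, root, tolerance = 1e-8)

  # rotating past the fully-closed configuration exceeds the mechanism
  th0_deg <- acos((rig$b^2 + rig$r^2 - 80^2) / (2 * rig$b * rig$r)) * 180 / pi
  expect_error(compute_delta_x(rig, -(th0_deg + 0.001), c_current = 80),
               class = "teaprof_mechanism_limit")
})

test_that("forward-inverse round trip holds across the linkage parameter grid", {
  for (b in c(30, 40, 60)) for (r in c(90, 114, 150)) for (cc in c(70, 80, 110)) {
    if (!(abs(b - r) < cc && cc < b + r)) next
    rg <- rig_config(b = b, r = r, c_zero = cc)
    for (alpha in c(-10, -2, 0, 1, 7.5, 20)) {
      dx <- tryCatch(compute_delta_x(rg, alpha, cc),
                     teaprof_mechanism_limit = function(e) NULL)
      if (is.null(dx)) next
      back <- alpha_from_delta_x(rg, dx, cc)
      expect_equal(back, alpha, tolerance = 1e-9)
    }
  }
})

test_that("the decision table reproduces the printed band cases", {
  tbl <- default_decision_table()
  dec <- decide_motion(tbl, 45, 53)
  expect_identical(dec$vertical, "hold")
  expect_identical(dec$rotation, "hold")

  dec <- decide_motion(tbl, 37, 53)
  expect_identical(dec$vertical, "rise")
  expect_identical(dec$rotation, "rotate_down")

  dec <- decide_motion(tbl, 500, 53)
  expect_identical(dec$vertical, "out_of_range")
  expect_identical(dec$rotation, "hold")
})

test_that("table validation rejects gaps, overlaps and incomplete rule grids", {
  tbl <- default_decision_table()
  expect_s3_class(validate_decision_table(tbl), "decision_table")

  overlapping <- tbl
  overlapping$near_bands$hi[1] <- 44   # low band now overlaps ideal
  expect_error(validate_decision_table(overlapping),
               class = "teaprof_config_error")

  gapped <- tbl
  gapped$far_bands$lo[2] <- 52         # hole between low and ideal
  expect_error(validate_decision_table(gapped),
               class = "teaprof_config_error")

  incomplete <- tbl
  incomplete$rules <- incomplete$rules[-1, ]
  expect_error(validate_decision_table(incomplete),
               class = "teaprof_config_error")

  # property: perturbing any interior band boundary breaks contiguity
  set.seed(23)
  for (i in 1:20) {
    bad <- default_decision_table()
    axis <- sample(c("near_bands", "far_bands"), 1)
    row <- sample(2:3, 1)     # interior boundaries must match the previous hi
    shift <- runif(1, 0.2, 3) * sample(c(-1, 1), 1)
    bad[[axis]]$lo[row] <- bad[[axis]]$lo[row] + shift
    expect_error(validate_decision_table(bad), class = "teaprof_config_error")
  }
})

test_that("pose pipeline combines adjustments, decision and no-op flagging", {
  res <- pose_pipeline(rig, l_near = 45.9412, l_far = 51.5316)
  expect_equal(res$d, -0.9412, tolerance = 1e-12)
  expect_identical(res$decision$vertical, "hold")

  res <- pose_pipeline(rig, l_near = 43.0867, l_far = 48.8257)
  expect_equal(res$d, 1.9133, tolerance = 1e-12)

  res <- pose_pipeline(rig, l_near = 45, l_far = 51)
  expect_identical(res$decision$vertical, "hold")
  expect_identical(res$decision$rotation, "hold")
  expect_true(res$no_op)
  expect_lte(abs(res$d), 2)   # no-op implies |d| within the band half-width

  # exact ideal point: fixed point of the whole computation
  res <- pose_pipeline(rig, l_near = rig$a_near - rig$L, l_far = rig$a_far - rig$L)
  expect_equal(res$d, 0)
  expect_equal(res$alpha, 0)
  expect_equal(res$delta_x, 0, tolerance = 1e-12)
})

test_that("one pose correction converges a tilted canopy to the no-op band", {
  mk <- function(peak) scene_params(
    canopy_arc_peak_depth = peak, canopy_arc_sag = 13, tilt = 0,
    depth_noise_sd = 0, hole_fraction = 0, illumination = "low", seed = 21)
  r1 <- run_frame(generate_canopy_frame(mk(40))$frame)
  expect_identical(r1$vertical, "rise")
  expect_identical(r1$rotation, "rotate_down")
  # rising by d raises the camera with the cutter: depths grow by d
  r2 <- run_frame(generate_canopy_frame(mk(40 + r1$d))$frame)
  expect_identical(r2$vertical, "hold")
  expect_identical(r2$rotation, "hold")
  expect_lte(abs(r2$d), 2)
})
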