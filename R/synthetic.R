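#' Synthetic canopy scene parameters
#'
#' Controls the seeded generator of RGB-D canopy frames with exact ground
#' truth. The rendered scene emulates a nadir view of a tea canopy: bright
#' green shoot blobs (overlapping ellipses with per-blob green jitter) over
#' darker old-leaf texture, a symmetric convex arc depth profile with
#' optional linear tilt, old leaves sitting below the shoot surface, global
#' illumination scaled so the frame's AG value lands in the requested
#' lighting band, and optional saturated specular patches.
#'
#' The depth surface (cm, before noise) is
#' `depth(u) = peak + sag * u^2 + tilt * u` with `u` in (-1, 1) the
#' normalized horizontal offset from the image centre; old-leaf pixels are
#' offset `old_leaf_depth_offset` deeper. Depth rasters are quantized to
#' integer millimetres; 0 is the invalid sentinel.
#'
#' @param image_height,image_width frame size in pixels (>= 64).
#' @param canopy_arc_peak_depth camera-to-apex distance in cm (> 0).
#' @param canopy_arc_sag depth increase at the image edge in cm (arc
#'   curvature, >= 0).
#' @param tilt left-right linear depth offset in cm (slope emulation).
#' @param shoot_density target fraction of the frame covered by shoots.
#' @param shoot_green_level base 8-bit G intensity of shoot pixels.
#' @param old_leaf_darkening multiplicative darkening of old leaves, (0, 1).
#' @param old_leaf_depth_offset cm old leaves sit below the shoot surface.
#' @param illumination `"low"` or `"high"` lighting band.
#' @param specular_fraction fraction of pixels in saturated highlight
#'   patches (high light).
#' @param depth_noise_sd Gaussian depth noise in mm.
#' @param hole_fraction fraction of depth pixels dropped to the invalid
#'   sentinel.
#' @param seed integer; one RNG stream per frame, global state untouched.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_height = 240L, image_width = 320L,
                         canopy_arc_peak_depth = 45, canopy_arc_sag = 6,
                         tilt = 0, shoot_density = 0.45,
                         shoot_green_level = 170, old_leaf_darkening = 0.55,
                         old_leaf_depth_offset = 6,
                         illumination = c("low", "high"),
                         specular_fraction = 0, depth_noise_sd = 3,
                         hole_fraction = 0.02, seed = 1L) {
  check_scalar(image_height, "image_height", lo = 64, integer = TRUE)
  check_scalar(image_width, "image_width", lo = 64, integer = TRUE)
  check_scalar(canopy_arc_peak_depth, "canopy_arc_peak_depth", lo = 1e-9)
  check_scalar(canopy_arc_sag, "canopy_arc_sag", lo = 0)
  check_scalar(tilt, "tilt")
  check_scalar(shoot_density, "shoot_density", 0, 1)
  check_scalar(shoot_green_level, "shoot_green_level", 1, 255)
  check_scalar(old_leaf_darkening, "old_leaf_darkening", 1e-9, 1)
  check_scalar(old_leaf_depth_offset, "old_leaf_depth_offset", lo = 0)
  illumination <- match.arg(illumination)
  check_scalar(specular_fraction, "specular_fraction", 0, 1)
  check_scalar(depth_noise_sd, "depth_noise_sd", lo = 0)
  check_scalar(hole_fraction, "hole_fraction", 0, 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         canopy_arc_peak_depth = canopy_arc_peak_depth,
         canopy_arc_sag = canopy_arc_sag, tilt = tilt,
         shoot_density = shoot_density,
         shoot_green_level = shoot_green_level,
         old_leaf_darkening = old_leaf_darkening,
         old_leaf_depth_offset = old_leaf_depth_offset,
         illumination = illumination,
         specular_fraction = specular_fraction,
         depth_noise_sd = depth_noise_sd, hole_fraction = hole_fraction,
         seed = as.integer(seed)),
    class = "scene_params"
  )
}

# Union of random ellipses until the target cover fraction is reached.
# Bulk shoots spread over the whole canopy top, so each measurement region
# is also topped up to a minimum shoot coverage.
render_shoot_blobs <- function(h, w, density, regions = list()) {
  mask <- matrix(FALSE, h, w)
  green_jitter <- matrix(0, h, w)
  if (density <= 0) return(list(mask = mask, green_jitter = green_jitter))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  scale <- min(h, w) / 240
  add_blob <- function(cx, cy) {
    a <- stats::runif(1, 18, 40) * scale
    b <- stats::runif(1, 14, 30) * scale
    th <- stats::runif(1, 0, pi)
    jit <- stats::runif(1, -15, 15)
    xr <- (cols - cx) * cos(th) + (rows - cy) * sin(th)
    yr <- -(cols - cx) * sin(th) + (rows - cy) * cos(th)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    green_jitter[inside & !mask] <<- jit
    mask <<- mask | inside
  }
  for (i in seq_len(600)) {
    if (mean(mask) >= density) break
    add_blob(stats::runif(1, 1, w), stats::runif(1, 1, h))
  }
  for (region in regions) {
    px <- region_pixel_bounds(region, c(h, w))
    for (i in seq_len(50)) {
      if (mean(mask[px$rows, px$cols]) >= min(density, 0.2)) break
      add_blob(stats::runif(1, min(px$cols), max(px$cols)),
               stats::runif(1, min(px$rows), max(px$rows)))
    }
  }
  list(mask = mask, green_jitter = green_jitter)
}

# Coarse luminance-correlated texture, upsampled to full resolution.
render_lowfreq_noise <- function(h, w, amplitude, cell = 8L) {
  gh <- ceiling(h / cell); gw <- ceiling(w / cell)
  grid <- matrix(stats::runif(gh * gw, -amplitude, amplitude), gh, gw)
  up <- grid[rep(seq_len(gh), each = cell)[seq_len(h)],
             rep(seq_len(gw), each = cell)[seq_len(w)]]
  up
}

# Disc-shaped saturated patches covering ~ frac of the frame.
render_specular_patches <- function(h, w, frac) {
  mask <- matrix(FALSE, h, w)
  if (frac <= 0) return(mask)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  radius <- max(3, round(min(h, w) / 30))
  for (i in seq_len(400)) {
    if (mean(mask) >= frac) break
    cx <- stats::runif(1, 1, w)
    cy <- stats::runif(1, 1, h)
    rr <- radius * stats::runif(1, 0.6, 1.4)
    mask <- mask | ((cols - cx)^2 + (rows - cy)^2 <= rr^2)
  }
  mask
}

# Find the global gain putting the frame's AG at `target`. Specular pixels
# are saturated and do not scale; deterministic bisection on the clamped
# luminance mean, which is nondecreasing in the gain.
calibrate_gain <- function(base, specular, specular_rgb, target) {
  ag_at <- function(g) {
    img <- pmin(pmax(base * g, 0), 255)
    if (any(specular)) for (ch in 1:3) img[, , ch][specular] <- specular_rgb[, , ch][specular]
    mean(luminance(round(img)))
  }
  lo <- 0.05; hi <- 6
  if (ag_at(hi) < target || ag_at(lo) > target)
    abort_teaprof("illumination calibration cannot reach the requested AG band",
                  "teaprof_parameter_error")
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (ag_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate one synthetic RGB-D canopy frame with ground truth
#'
#' Deterministic for a given seed. The ground-truth depth pair
#' (`true_l_near`, `true_l_far`) is the exact area-weighted mean of the
#' noise-free shoot surface over the configured regions restricted to shoot
#' pixels, and `true_d` / `true_alpha` follow from the rig geometry — so
#' every downstream stage can be scored against known values.
#'
#' @param params a [scene_params()].
#' @param rig a [rig_config()] used for the truth pose.
#' @param near_region,far_region [region_spec()]s the truth depths are
#'   averaged over.
#' @return list with `frame` (a [canopy_frame()]) and `truth` (class
#'   `canopy_truth`: `shoot_mask`, `specular_mask`, `true_l_near`,
#'   `true_l_far`, `true_d`, `true_alpha`).
#' @export
generate_canopy_frame <- function(params = scene_params(), rig = rig_config(),
                                  near_region = near_region_default(),
                                  far_region = far_region_default()) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_height; w <- params$image_width
  with_local_seed(params$seed, {
    blobs <- render_shoot_blobs(h, w, params$shoot_density,
                                regions = list(near_region, far_region))
    shoot <- blobs$mask

    # depth surface in cm: arc + tilt over the normalized horizontal offset
    u <- 2 * (seq_len(w) - 0.5) / w - 1
    surf_cm <- params$canopy_arc_peak_depth +
      params$canopy_arc_sag * u^2 + params$tilt * u
    surface <- matrix(surf_cm, h, w, byrow = TRUE)
    depth_cm <- surface + params$old_leaf_depth_offset * !shoot
    depth_mm <- depth_cm * 10 +
      if (params$depth_noise_sd > 0)
        matrix(stats::rnorm(h * w, 0, params$depth_noise_sd), h, w)
      else 0
    depth_mm <- pmin(pmax(round(depth_mm), 1), 65535)
    if (params$hole_fraction > 0) {
      holes <- matrix(stats::runif(h * w) < params$hole_fraction, h, w)
      depth_mm[holes] <- 0
    }

    # base colour (pre-illumination): strongly green shoots, darkened leaves
    g0 <- params$shoot_green_level
    base <- array(0, dim = c(h, w, 3))
    shoot_g <- pmin(pmax(g0 + blobs$green_jitter, 40), 255)
    dk <- params$old_leaf_darkening
    # Old-leaf brightness varies patchwise (shading), but with channel
    # weights (2, 1, 1) the patches are neutral in the excess-green index:
    # greenness variation on old leaves is per-pixel only, so threshold
    # noise stays isolated and erodible.
    leaf_tex <- render_lowfreq_noise(h, w, amplitude = 6)
    base[, , 1] <- ifelse(shoot, 0.45 * shoot_g, dk * 70 + 2 * leaf_tex)
    base[, , 2] <- ifelse(shoot, shoot_g, dk * 110 + leaf_tex)
    base[, , 3] <- ifelse(shoot, 0.40 * shoot_g, dk * 65 + leaf_tex)
    pixel_noise <- array(stats::rnorm(h * w * 3, 0, 6), dim = c(h, w, 3))
    base <- base + pixel_noise
    # keep the channel ordering (G > R, G > B) strict on shoot pixels
    eps <- 1
    base[, , 1] <- ifelse(shoot, pmin(base[, , 1], base[, , 2] - eps), base[, , 1])
    base[, , 3] <- ifelse(shoot, pmin(base[, , 3], base[, , 2] - eps), base[, , 3])
    base <- pmin(pmax(base, 1), 255)

    specular <- render_specular_patches(h, w, params$specular_fraction)
    specular_rgb <- array(0, dim = c(h, w, 3))
    if (any(specular)) {
      for (ch in 1:3) {
        v <- matrix(stats::runif(h * w, 243, 255), h, w)
        specular_rgb[, , ch] <- v
      }
    }

    target_ag <- if (params$illumination == "low") 120 else 168
    gain <- calibrate_gain(base, specular, specular_rgb, target_ag)
    rgb <- pmin(pmax(base * gain, 0), 255)
    if (any(specular)) for (ch in 1:3) rgb[, , ch][specular] <- specular_rgb[, , ch][specular]
    rgb <- round(rgb)

    # generator self-check: AG must land in the requested band
    ag <- mean(luminance(rgb))
    band_ok <- if (params$illumination == "low") ag >= 90 && ag < 140
               else ag >= 140 && ag <= 220
    if (!band_ok)
      abort_teaprof(sprintf("generator self-check failed: AG %.1f outside the %s band",
                            ag, params$illumination), "teaprof_parameter_error")

    truth_mean <- function(region) {
      px <- region_pixel_bounds(region, c(h, w))
      sel <- shoot[px$rows, px$cols, drop = FALSE]
      s <- surface[px$rows, px$cols, drop = FALSE]
      if (!any(sel)) mean(s) else mean(s[sel])
    }
    l_near <- truth_mean(near_region)
    l_far <- truth_mean(far_region)

    frame <- canopy_frame(rgb, depth_mm,
                          frame_id = sprintf("synth-%d", params$seed),
                          params = params)
    truth <- structure(
      list(shoot_mask = shoot, specular_mask = specular,
           true_l_near = l_near, true_l_far = l_far,
           true_d = compute_d(rig, l_near),
           true_alpha = compute_alpha(rig, l_far)),
      class = "canopy_truth"
    )
    list(frame = frame, truth = truth)
  })
}

#' Pixel-aligned RGB + depth observation
#'
#' @param rgb H x W x 3 array of 8-bit intensities.
#' @param depth H x W matrix of depths in integer mm (0 = invalid), same
#'   shape as `rgb`.
#' @param frame_id identifier string.
#' @param timestamp optional timestamp.
#' @param params optional [scene_params()] provenance (synthetic frames).
#' @return object of class `canopy_frame`.
#' @export
canopy_frame <- function(rgb, depth, frame_id = "frame", timestamp = NULL,
                         params = NULL) {
  check_rgb_image(rgb)
  check_depth(depth)
  if (!all(dim(depth) == dim(rgb)[1:2]))
    abort_parameter("rgb and depth must be pixel-aligned (same shape)")
  structure(list(rgb = rgb, depth = depth, frame_id = frame_id,
                 timestamp = timestamp, params = params),
            class = "canopy_frame")
}

#' @export
print.canopy_frame <- function(x, ...) {
  cat(sprintf("<canopy_frame> %s: %d x %d, depth %d-%d mm (%.1f%% invalid)\n",
              x$frame_id, nrow(x$depth), ncol(x$depth),
              min(x$depth[x$depth > 0]), max(x$depth),
              100 * mean(x$depth == 0)))
  invisible(x)
}
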