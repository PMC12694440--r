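#' Segmentation configuration
#'
#' Tunable parameters of the shoot segmenter. The defaults follow the
#' deployed pipeline: CLAHE with clip limit 2.0 on an 8 x 8 tile grid for
#' low-light frames, a specular rule marking pixels whose darkest channel
#' reaches 230, a 3 x 3 erosion pass, and average-grayscale (AG) lighting
#' bands of \[90, 140) for low light and \[140, 220\] for high light.
#'
#' @param clahe_clip_limit CLAHE contrast clip limit (unitless).
#' @param clahe_tile number of CLAHE tiles along each image axis.
#' @param specular_threshold 8-bit intensity; a pixel is specular when its
#'   minimum channel value is at or above this.
#' @param erosion_kernel side of the square structuring element (odd pixels).
#' @param erosion_iterations number of erosion passes.
#' @param ag_low,ag_mid,ag_high AG band edges: low light is `[ag_low, ag_mid)`,
#'   high light `[ag_mid, ag_high]`.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(clahe_clip_limit = 2.0, clahe_tile = 8L,
                                specular_threshold = 230, erosion_kernel = 3L,
                                erosion_iterations = 1L,
                                ag_low = 90, ag_mid = 140, ag_high = 220) {
  check_scalar(clahe_clip_limit, "clahe_clip_limit", lo = 0)
  check_scalar(clahe_tile, "clahe_tile", lo = 1, integer = TRUE)
  check_scalar(specular_threshold, "specular_threshold", lo = 0, hi = 255)
  check_scalar(erosion_kernel, "erosion_kernel", lo = 1, integer = TRUE)
  if (erosion_kernel %% 2 == 0)
    abort_parameter("`erosion_kernel` must be odd")
  check_scalar(erosion_iterations, "erosion_iterations", lo = 0, integer = TRUE)
  check_scalar(ag_low, "ag_low", 0, 255)
  check_scalar(ag_mid, "ag_mid", 0, 255)
  check_scalar(ag_high, "ag_high", 0, 255)
  if (!(ag_low < ag_mid && ag_mid <= ag_high))
    abort_parameter("AG bands require ag_low < ag_mid <= ag_high")
  structure(
    list(clahe_clip_limit = clahe_clip_limit, clahe_tile = as.integer(clahe_tile),
         specular_threshold = specular_threshold,
         erosion_kernel = as.integer(erosion_kernel),
         erosion_iterations = as.integer(erosion_iterations),
         ag_low = ag_low, ag_mid = ag_mid, ag_high = ag_high),
    class = "segmentation_config"
  )
}

#' Average grayscale (AG) of a frame
#'
#' Mean of the standard-luminance grayscale conversion
#' (0.299 R + 0.587 G + 0.114 B) over the frame, or over an optional
#' sub-region. AG drives the choice between the low-light and high-light
#' segmentation branches.
#'
#' @param image H x W x 3 array of 8-bit intensities (R, G, B).
#' @param region optional [region_spec()] restricting the average.
#' @return mean grayscale in \[0, 255\].
#' @export
average_gray <- function(image, region = NULL) {
  check_rgb_image(image)
  lum <- luminance(image)
  if (!is.null(region)) {
    px <- region_pixel_bounds(region, dim(lum))
    lum <- lum[px$rows, px$cols, drop = FALSE]
  }
  mean(lum)
}

#' Classify a frame's lighting regime from its AG value
#'
#' Frames with AG in `[ag_low, ag_mid)` are low light (overcast/cloudy),
#' `[ag_mid, ag_high]` high light (sunny, specular highlights expected);
#' anything else is `out_of_range` — a value, not an error, so callers can
#' decide how to proceed.
#'
#' @param ag mean grayscale in \[0, 255\].
#' @param cfg a [segmentation_config()].
#' @return object of class `lighting_class` with fields `label`
#'   (`"low_light"`, `"high_light"` or `"out_of_range"`) and `ag_value`.
#' @export
classify_lighting <- function(ag, cfg = segmentation_config()) {
  check_scalar(ag, "ag", 0, 255)
  label <- if (ag >= cfg$ag_low && ag < cfg$ag_mid) "low_light"
    else if (ag >= cfg$ag_mid && ag <= cfg$ag_high) "high_light"
    else "out_of_range"
  structure(list(label = label, ag_value = ag), class = "lighting_class")
}

#' @export
print.lighting_class <- function(x, ...) {
  cat(sprintf("<lighting_class> %s (AG = %.2f)\n", x$label, x$ag_value))
  invisible(x)
}

#' Super-green (excess-green) index image
#'
#' Per pixel computes `2 G - R/2 - B` in floating point, clamps to
#' \[0, 255\] and quantizes to 8 bit. Vegetation (G well above R and B) maps
#' to high values while shaded older leaves map low, so the index histogram
#' of a canopy frame is near-bimodal and suited to Otsu thresholding.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @return H x W matrix of 8-bit index values.
#' @export
supergreen <- function(image) {
  check_rgb_image(image)
  g <- 2 * image[, , 2] - image[, , 1] / 2 - image[, , 3]
  matrix(round(pmin(pmax(g, 0), 255)), dim(image)[1], dim(image)[2])
}

#' Contrast-limited adaptive histogram equalization of the luminance
#'
#' Applies CLAHE to the luminance component and rescales the colour channels
#' by the luminance gain so chromaticity is preserved. Used on low-light
#' frames to restore the shoot/old-leaf contrast before the super-green
#' conversion.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param cfg a [segmentation_config()] supplying clip limit and tile grid.
#' @return enhanced H x W x 3 array of 8-bit intensities.
#' @export
clahe_enhance <- function(image, cfg = segmentation_config()) {
  check_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < cfg$clahe_tile || w < cfg$clahe_tile)
    abort_parameter(sprintf(
      "image (%d x %d) is smaller than the %d x %d CLAHE tile grid",
      h, w, cfg$clahe_tile, cfg$clahe_tile))
  y <- luminance(image)
  # EBImage stores images x-major, hence the transposes.
  yc <- EBImage::clahe(EBImage::Image(t(y) / 255),
                       nx = cfg$clahe_tile, ny = cfg$clahe_tile,
                       limit = cfg$clahe_clip_limit)
  yc <- t(EBImage::imageData(yc)) * 255
  gain <- ifelse(y > 0, yc / y, 1)
  out <- image
  for (ch in 1:3) out[, , ch] <- round(pmin(pmax(image[, , ch] * gain, 0), 255))
  out
}

#' Mark specular (saturated highlight) pixels
#'
#' A pixel is specular when all three channels are at or above the configured
#' threshold, i.e. its minimum channel value reaches `specular_threshold`.
#' The high-light branch zeroes these pixels before the super-green
#' conversion and excludes gray level 0 from Otsu.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param cfg a [segmentation_config()].
#' @return H x W logical matrix, `TRUE` for specular pixels.
#' @export
specular_mask <- function(image, cfg = segmentation_config()) {
  check_rgb_image(image)
  pmin(image[, , 1], image[, , 2], image[, , 3]) >= cfg$specular_threshold
}

#' Otsu threshold with optional zero exclusion
#'
#' Exhaustively scans the 8-bit gray levels and returns the threshold `t`
#' that maximizes the between-class variance of the split into levels
#' `<= t` and `> t`; ties break toward the lower threshold. With
#' `exclude_zero = TRUE`, gray level 0 is dropped from the histogram first —
#' the variant used on high-light frames where specular pixels have been
#' zeroed and must not influence the split.
#'
#' @param gray H x W matrix of 8-bit intensities (quantized to integers).
#' @param exclude_zero drop gray level 0 from the histogram?
#' @return integer threshold in 0..254; foreground is `gray > threshold`.
#' @export
otsu_threshold <- function(gray, exclude_zero = FALSE) {
  check_gray_image(gray)
  counts <- tabulate(as.integer(round(gray)) + 1L, nbins = 256L)
  if (exclude_zero) counts[1L] <- 0L
  if (sum(counts > 0L) < 2L)
    abort_teaprof(
      "degenerate histogram: fewer than two distinct eligible gray levels",
      "teaprof_degenerate_histogram")
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)                 # pixels at levels <= t
  s0 <- cumsum(counts * levels)        # intensity sum at levels <= t
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (s0[256] - s0) / w1, 0)
  sigma_b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf   # both classes must be non-empty
  which.max(sigma_b) - 1L              # which.max takes the first (lowest) tie
}

#' Erode a binary mask with a square structuring element
#'
#' Morphological erosion removes isolated small regions and thins thin
#' structures, cleaning residual noise after thresholding. The structuring
#' element is a square of side `erosion_kernel`, applied
#' `erosion_iterations` times; output foreground is always a subset of the
#' input foreground.
#'
#' @param mask H x W logical (or 0/1) matrix.
#' @param cfg a [segmentation_config()].
#' @return H x W logical matrix.
#' @export
morphological_erode <- function(mask, cfg = segmentation_config()) {
  m <- check_mask(mask)
  if (cfg$erosion_iterations == 0L) return(m)
  kern <- EBImage::makeBrush(cfg$erosion_kernel, shape = "box")
  img <- EBImage::Image(t(m) * 1)
  for (i in seq_len(cfg$erosion_iterations)) img <- EBImage::erode(img, kern)
  t(EBImage::imageData(img)) > 0.5
}

#' Segment bulk tea shoots in an RGB canopy frame
#'
#' Full two-branch detector. The frame's AG value selects the branch:
#' low light applies CLAHE, the super-green index, plain Otsu and erosion;
#' high light first marks and zeroes specular pixels, computes the index,
#' thresholds with zero-excluding Otsu, erodes, and forces specular pixels
#' to background. Foreground is the bright class of the index (the shoots).
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param cfg a [segmentation_config()].
#' @param force_class optional `"low_light"` or `"high_light"` to override
#'   the AG dispatch (e.g. for frames just outside the calibrated bands).
#' @return object of class `shoot_mask`: fields `mask` (logical H x W),
#'   `lighting` ([classify_lighting()] result), `threshold` (Otsu level),
#'   `foreground_fraction`.
#' @export
segment_shoots <- function(image, cfg = segmentation_config(), force_class = NULL) {
  check_rgb_image(image)
  ag <- average_gray(image)
  lighting <- classify_lighting(ag, cfg)
  label <- lighting$label
  if (!is.null(force_class)) {
    if (!force_class %in% c("low_light", "high_light"))
      abort_parameter("`force_class` must be \"low_light\" or \"high_light\"")
    label <- force_class
  }
  if (label == "out_of_range")
    abort_teaprof(
      sprintf("AG %.1f is outside the calibrated lighting bands [%g, %g]; use `force_class` to override",
              ag, cfg$ag_low, cfg$ag_high),
      "teaprof_lighting_error", ag = ag)

  if (label == "low_light") {
    g <- supergreen(clahe_enhance(image, cfg))
    thr <- otsu_threshold(g, exclude_zero = FALSE)
    fg <- g > thr
  } else {
    sp <- specular_mask(image, cfg)
    img0 <- image
    for (ch in 1:3) img0[, , ch][sp] <- 0
    g <- supergreen(img0)
    g[sp] <- 0                       # specular pixels carry gray value 0
    thr <- otsu_threshold(g, exclude_zero = TRUE)
    fg <- g > thr & !sp
  }
  fg <- morphological_erode(fg, cfg)
  if (label == "high_light") fg <- fg & !sp
  structure(
    list(mask = fg,
         lighting = structure(list(label = label, ag_value = ag),
                              class = "lighting_class"),
         threshold = thr,
         foreground_fraction = mean(fg)),
    class = "shoot_mask"
  )
}

#' @export
print.shoot_mask <- function(x, ...) {
  cat(sprintf("<shoot_mask> %d x %d, %s (AG %.1f), Otsu %d, foreground %.1f%%\n",
              nrow(x$mask), ncol(x$mask), x$lighting$label, x$lighting$ag_value,
              x$threshold, 100 * x$foreground_fraction))
  invisible(x)
}
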