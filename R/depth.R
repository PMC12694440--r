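#' Depth preprocessing configuration
#'
#' Plausible-range gate, median-filter kernel and the minimum number of
#' contributing pixels a region average needs. Units are millimetres
#' throughout the raster interface; region means are reported in
#' centimetres. The default gate \[200, 2000\] mm brackets the working
#' camera-to-canopy distances of a cutter-mounted nadir camera.
#'
#' @param min_depth_mm,max_depth_mm plausible depth range; anything outside
#'   (including the 0 invalid sentinel) is marked invalid.
#' @param median_kernel odd side of the median-filter window (pixels).
#' @param min_valid_pixels minimum contributor count for a region average.
#' @return object of class `depth_filter_config`.
#' @export
depth_filter_config <- function(min_depth_mm = 200, max_depth_mm = 2000,
                                median_kernel = 5L, min_valid_pixels = 25L) {
  check_scalar(min_depth_mm, "min_depth_mm", lo = 0)
  check_scalar(max_depth_mm, "max_depth_mm", lo = 0)
  if (!(min_depth_mm > 0 && min_depth_mm < max_depth_mm))
    abort_parameter("depth gate requires 0 < min_depth_mm < max_depth_mm")
  check_scalar(median_kernel, "median_kernel", lo = 1, integer = TRUE)
  if (median_kernel %% 2 == 0) abort_parameter("`median_kernel` must be odd")
  check_scalar(min_valid_pixels, "min_valid_pixels", lo = 1, integer = TRUE)
  structure(
    list(min_depth_mm = min_depth_mm, max_depth_mm = max_depth_mm,
         median_kernel = as.integer(median_kernel),
         min_valid_pixels = as.integer(min_valid_pixels)),
    class = "depth_filter_config"
  )
}

check_depth <- function(depth, arg = "depth") {
  if (!is.matrix(depth) || length(depth) == 0L)
    abort_parameter(sprintf("`%s` must be a non-empty matrix of depths in mm", arg))
  if (anyNA(depth) || min(depth) < 0)
    abort_parameter(sprintf("`%s` must be non-negative (0 = invalid sentinel)", arg))
  invisible(depth)
}

#' Gate a depth raster to its plausible range
#'
#' Pixels outside `[min_depth_mm, max_depth_mm]` — holes (the 0 sentinel),
#' dropouts, and far outliers such as ground seen through the canopy — are
#' set to the invalid sentinel 0; in-range pixels pass through unchanged.
#'
#' @param depth H x W matrix of depths in mm (0 = invalid).
#' @param cfg a [depth_filter_config()].
#' @return gated H x W depth matrix.
#' @export
filter_depth <- function(depth, cfg = depth_filter_config()) {
  check_depth(depth)
  out <- depth
  out[depth < cfg$min_depth_mm | depth > cfg$max_depth_mm] <- 0
  out
}

#' Median-smooth a depth raster, ignoring invalid pixels
#'
#' Classical median filtering suppresses residual salt noise, but the
#' invalid sentinel must not leak into the medians: each window's median is
#' taken over the *valid* pixels only, and invalid pixels stay invalid.
#' A valid pixel always has at least itself in its window.
#'
#' @param depth H x W matrix of depths in mm (0 = invalid).
#' @param cfg a [depth_filter_config()]; `median_kernel` sets the window.
#' @return smoothed H x W depth matrix, same invalid pattern as the input.
#' @export
median_smooth <- function(depth, cfg = depth_filter_config()) {
  check_depth(depth)
  k <- cfg$median_kernel
  if (k == 1L) return(depth)
  h <- nrow(depth); w <- ncol(depth)
  r <- (k - 1L) %/% 2L
  x <- depth
  x[x == 0] <- NA_real_
  # Stack the k^2 window shifts; borders are padded with NA (absent).
  stack <- array(NA_real_, dim = c(h, w, k * k))
  s <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    s <- s + 1L
    src_r <- max(1L, 1L - dy):min(h, h - dy)
    src_c <- max(1L, 1L - dx):min(w, w - dx)
    stack[src_r, src_c, s] <- x[src_r + dy, src_c + dx]
  }
  med <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  out <- depth
  valid <- depth > 0
  out[valid] <- med[valid]
  out
}

#' Rectangular region of interest as image fractions
#'
#' Regions are expressed as fractions of the image extent so the same
#' configuration applies at any resolution. Defaults for the two
#' pose-driving regions: the central (`l_near`) region spans columns
#' 4/14–10/14 and rows 3/8–5/8; the left (`l_far`) region spans columns
#' 1/14–2/14 and rows 3/8–5/8.
#'
#' @param col_lo,col_hi,row_lo,row_hi fractions in \[0, 1\], `lo < hi`.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(col_lo, col_hi, row_lo, row_hi) {
  for (f in c("col_lo", "col_hi", "row_lo", "row_hi"))
    check_scalar(get(f), f, 0, 1)
  if (!(col_lo < col_hi && row_lo < row_hi))
    abort_parameter("region requires col_lo < col_hi and row_lo < row_hi")
  structure(list(col_lo = col_lo, col_hi = col_hi,
                 row_lo = row_lo, row_hi = row_hi),
            class = "region_spec")
}

#' @rdname region_spec
#' @export
near_region_default <- function() region_spec(4 / 14, 10 / 14, 3 / 8, 5 / 8)

#' @rdname region_spec
#' @export
far_region_default <- function() region_spec(1 / 14, 2 / 14, 3 / 8, 5 / 8)

# Fractions -> half-open pixel index ranges: floor(lo * extent) .. floor(hi * extent),
# half-open, i.e. 1-based rows (floor(lo*H)+1) : floor(hi*H).
region_pixel_bounds <- function(region, dim) {
  h <- dim[1]; w <- dim[2]
  rows <- (floor(region$row_lo * h) + 1L):floor(region$row_hi * h)
  cols <- (floor(region$col_lo * w) + 1L):floor(region$col_hi * w)
  if (length(rows) < 1L || length(cols) < 1L ||
      floor(region$row_hi * h) <= floor(region$row_lo * h) ||
      floor(region$col_hi * w) <= floor(region$col_lo * w))
    abort_parameter("region contains no pixels at this resolution")
  list(rows = rows, cols = cols)
}

#' Mean shoot depth over a fixed region
#'
#' Averages the depth of pixels that are (a) inside the region rectangle,
#' (b) shoot foreground in the mask, and (c) valid (non-zero after gating).
#' Averaging over a region rather than reading single pixels suppresses
#' per-pixel depth error; restricting to shoot pixels keeps the deeper old
#' leaves from dragging the mean away from the canopy surface.
#'
#' @param depth H x W matrix of depths in mm (already gated/smoothed).
#' @param mask [segment_shoots()] result or logical H x W matrix.
#' @param region a [region_spec()].
#' @param cfg a [depth_filter_config()]; `min_valid_pixels` is enforced.
#' @return mean depth in cm.
#' @export
region_mean_depth <- function(depth, mask, region, cfg = depth_filter_config()) {
  check_depth(depth)
  m <- check_mask(mask)
  if (!all(dim(m) == dim(depth)))
    abort_parameter("mask and depth raster must be pixel-aligned")
  px <- region_pixel_bounds(region, dim(depth))
  d <- depth[px$rows, px$cols, drop = FALSE]
  keep <- m[px$rows, px$cols, drop = FALSE] & d > 0
  n <- sum(keep)
  if (n < cfg$min_valid_pixels)
    abort_teaprof(
      sprintf("only %d valid shoot pixels in region (need >= %d)",
              n, cfg$min_valid_pixels),
      "teaprof_insufficient_evidence", n_valid = n)
  mean(d[keep]) / 10
}

#' Extract the pose-driving depth pair (l_near, l_far)
#'
#' Runs the depth preprocessing chain (plausible-range gate, invalid-aware
#' median smoothing) and averages the shoot depth over the central and left
#' regions. If a region holds fewer than `min_valid_pixels` shoot pixels,
#' the mean over *all* valid pixels in the region is used instead and
#' flagged — the machine must still produce a pose every frame.
#'
#' @param frame a [canopy_frame()] (or any list with a `depth` matrix in mm).
#' @param mask [segment_shoots()] result or logical matrix.
#' @param near_region,far_region [region_spec()]s for the central and left
#'   regions.
#' @param cfg a [depth_filter_config()].
#' @return object of class `depth_profile`: `l_near`, `l_far` (cm),
#'   contributor counts `n_near`, `n_far`, and logical `fallback_near`,
#'   `fallback_far`.
#' @export
extract_l_values <- function(frame, mask,
                             near_region = near_region_default(),
                             far_region = far_region_default(),
                             cfg = depth_filter_config()) {
  depth <- if (is.list(frame)) frame$depth else frame
  check_depth(depth)
  m <- check_mask(mask)
  depth <- median_smooth(filter_depth(depth, cfg), cfg)

  one <- function(region) {
    tryCatch({
      px <- region_pixel_bounds(region, dim(depth))
      d <- depth[px$rows, px$cols, drop = FALSE]
      keep <- m[px$rows, px$cols, drop = FALSE] & d > 0
      if (sum(keep) < cfg$min_valid_pixels)
        abort_teaprof("insufficient shoot evidence", "teaprof_insufficient_evidence")
      list(l = mean(d[keep]) / 10, n = sum(keep), fallback = FALSE)
    }, teaprof_insufficient_evidence = function(e) {
      px <- region_pixel_bounds(region, dim(depth))
      d <- depth[px$rows, px$cols, drop = FALSE]
      keep <- d > 0
      if (sum(keep) < 1L)
        abort_teaprof("region has no valid depth pixels at all",
                      "teaprof_insufficient_evidence")
      list(l = mean(d[keep]) / 10, n = sum(keep), fallback = TRUE)
    })
  }
  near <- one(near_region)
  far <- one(far_region)
  structure(
    list(l_near = near$l, l_far = far$l, n_near = near$n, n_far = far$n,
         fallback_near = near$fallback, fallback_far = far$fallback),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> l_near %.2f cm (n=%d%s), l_far %.2f cm (n=%d%s)\n",
              x$l_near, x$n_near, if (x$fallback_near) ", fallback" else "",
              x$l_far, x$n_far, if (x$fallback_far) ", fallback" else ""))
  invisible(x)
}
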